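## Benchmark-grid orchestration: plan enumeration over
## datasets x region sizes x depths x regions x tools, execution with the
## built-in aligner or external-tool adapters, Table-style summaries and
## the metaconsensus comparison.

#' Benchmark grid configuration
#'
#' The cross product driving a benchmark run. Defaults mirror the standard
#' grid: region sizes 100-10,000 bases, depths 10x-200x, 10 random regions
#' per combination, consensus threshold 70%.
#'
#' @param datasets character vector of dataset ids.
#' @param region_sizes region lengths in bases.
#' @param depths sequencing depths (MSA row counts).
#' @param n_regions regions (start positions) per combination.
#' @param tools MSA method names (`"builtin"` or adapter names).
#' @param threshold consensus threshold in `(0, 1]`.
#' @param seed integer seed for the whole grid.
#' @return an object of class `msab_grid_config`.
#' @examples
#' length_of_default_plan <- nrow(enumerate_plan(grid_config(
#'   datasets = c("d1", "d2", "d3", "d4"),
#'   tools = paste0("tool", 1:9))))
#' @export
grid_config <- function(datasets = "simulated",
                        region_sizes = c(100, 200, 500, 1000, 2000, 5000,
                                         10000),
                        depths = c(10, 20, 30, 45, 50, 60, 100, 150, 200),
                        n_regions = 10L,
                        tools = "builtin",
                        threshold = 0.7,
                        seed = 1L) {
  stopifnot(length(datasets) >= 1L, length(region_sizes) >= 1L,
            length(depths) >= 1L, n_regions >= 1L, length(tools) >= 1L,
            threshold > 0, threshold <= 1)
  structure(list(datasets = as.character(datasets),
                 region_sizes = as.integer(region_sizes),
                 depths = as.integer(depths),
                 n_regions = as.integer(n_regions),
                 tools = as.character(tools),
                 threshold = threshold, seed = as.integer(seed)),
            class = "msab_grid_config")
}

#' Enumerate the experiment plan of a grid
#'
#' Deterministic, dataset-major cross product of the grid dimensions; each
#' row is one experiment uniquely identified by (dataset, region size,
#' region index, depth, tool). The default four-dataset, nine-tool grid
#' yields 22,680 experiments.
#'
#' @param config a [grid_config()].
#' @return a `data.frame` with columns `dataset`, `size`, `region`,
#'   `depth`, `tool` and a per-experiment `seed`.
#' @export
enumerate_plan <- function(config) {
  stopifnot(inherits(config, "msab_grid_config"))
  plan <- expand.grid(tool = config$tools,
                      region = seq_len(config$n_regions),
                      depth = config$depths,
                      size = config$region_sizes,
                      dataset = config$datasets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plan <- plan[, c("dataset", "size", "region", "depth", "tool")]
  # dataset-major ordering; experiment seeds stay below 2^31
  plan <- plan[order(match(plan$dataset, config$datasets), plan$size,
                     plan$region, plan$depth,
                     match(plan$tool, config$tools)), , drop = FALSE]
  rownames(plan) <- NULL
  plan$seed <- (config$seed + seq_len(nrow(plan)) * 7919L) %% .Machine$integer.max
  plan
}

#' Simulated dataset configurations
#'
#' The standard simulated benchmark: the four error-type profiles (DEL,
#' INS, SUB, MIX) crossed with eight overall error rates (1, 2, 5, 10,
#' 15, 20, 25, 30%), i.e. 32 dataset configurations.
#'
#' @param kinds error-profile kinds.
#' @param rates overall error rates (fractions).
#' @return a `data.frame` with columns `dataset`, `kind`, `rate`.
#' @export
simulated_dataset_configs <- function(kinds = c("DEL", "INS", "SUB", "MIX"),
                                      rates = c(0.01, 0.02, 0.05, 0.10,
                                                0.15, 0.20, 0.25, 0.30)) {
  g <- expand.grid(rate = rates, kind = kinds,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(dataset = sprintf("%s_%g", g$kind, 100 * g$rate),
             kind = g$kind, rate = g$rate, stringsAsFactors = FALSE)
}

#' External MSA tool adapter
#'
#' Declares how to invoke an external MSA program: a command template with
#' `{input}` / `{output}` placeholders that turns a FASTA of reads into an
#' aligned FASTA. Adapter output is validated: its gap-stripped rows must
#' equal the input reads (row conservation), otherwise the experiment is
#' marked FAILED.
#'
#' @param name tool name.
#' @param template shell command with `{input}` and `{output}`
#'   placeholders (output may also be written to stdout with
#'   `{output}` omitted and `stdout = TRUE`).
#' @param stdout if `TRUE`, capture stdout as the aligned FASTA.
#' @return an object of class `msab_adapter`; callable through
#'   [run_adapter()].
#' @examples
#' mafft <- tool_adapter("mafft", "mafft --auto {input}", stdout = TRUE)
#' @export
tool_adapter <- function(name, template, stdout = FALSE) {
  structure(list(name = name, template = template, stdout = stdout),
            class = "msab_adapter")
}

adapter_available <- function(adapter) {
  prog <- strsplit(trimws(adapter$template), "\\s+")[[1]][1]
  nzchar(Sys.which(prog))
}

#' @rdname tool_adapter
#' @param adapter an `msab_adapter`.
#' @param reads named character vector of reads.
#' @return `run_adapter()`: an [msa()] whose rows strip to `reads`.
#' @export
run_adapter <- function(adapter, reads) {
  if (!adapter_available(adapter))
    stop("adapter binary not found: ", adapter$name)
  inp <- tempfile(fileext = ".fasta")
  on.exit(unlink(inp), add = TRUE)
  write_fasta(reads, inp)
  cmd <- gsub("{input}", inp, adapter$template, fixed = TRUE)
  if (adapter$stdout) {
    out <- tempfile(fileext = ".afa")
    on.exit(unlink(out), add = TRUE)
    status <- system(paste(cmd, ">", shQuote(out), "2>/dev/null"))
  } else {
    out <- tempfile(fileext = ".afa")
    on.exit(unlink(out), add = TRUE)
    cmd <- gsub("{output}", out, cmd, fixed = TRUE)
    status <- system(paste(cmd, "2>/dev/null"))
  }
  if (status != 0L) stop("adapter ", adapter$name, " exited with status ",
                         status)
  m <- read_msa_fasta(out)
  stripped <- gsub("-", "", m$rows, fixed = TRUE)
  # row conservation: same multiset of sequences (tools may reorder)
  if (!identical(sort(stripped), sort(unname(toupper(reads)))))
    stop("adapter ", adapter$name,
         " violated row conservation: gap-stripped MSA rows do not equal ",
         "the input reads")
  m
}

# resolve a tool name to a reads -> msa function
tool_fun <- function(tool, adapters = list(), sc = scoring()) {
  if (identical(tool, "builtin"))
    return(function(reads) center_star_msa(reads, sc))
  ad <- adapters[[tool]]
  if (is.null(ad)) stop("no adapter registered for tool ", sQuote(tool))
  function(reads) run_adapter(ad, reads)
}

#' Run one benchmark experiment
#'
#' Pipeline steps for a single (dataset, region, depth, tool) cell:
#' simulate (or accept) the reads, build the MSA, call the threshold
#' consensus and score it against the region's reference. Failures are
#' captured, not propagated, so a grid run survives individual tool
#' crashes.
#'
#' @param reads named character vector of reads for the region.
#' @param reference_segment the region's reference sequence.
#' @param tool tool name (`"builtin"` or a name in `adapters`).
#' @param threshold consensus threshold.
#' @param adapters named list of [tool_adapter()]s.
#' @param sc a [scoring()] object.
#' @return a one-row `data.frame`: `status` (`OK`/`SKIPPED`/`FAILED`),
#'   `reason`, and the [evaluate_consensus()] metrics (NA unless OK).
#' @export
run_experiment <- function(reads, reference_segment, tool = "builtin",
                           threshold = 0.7, adapters = list(),
                           sc = scoring()) {
  empty <- evaluate_consensus("A", "A", sc)[0, ]
  blank <- as.data.frame(as.list(stats::setNames(
    rep(NA_real_, ncol(empty)), names(empty))))
  res <- tryCatch({
    m <- tool_fun(tool, adapters, sc)(reads)
    cons <- msa_consensus(m, threshold)
    metrics <- evaluate_consensus(cons$ungapped, reference_segment, sc)
    cbind(data.frame(status = "OK", reason = ""), metrics)
  }, error = function(e) {
    status <- if (grepl("binary not found", conditionMessage(e)))
      "SKIPPED" else "FAILED"
    cbind(data.frame(status = status, reason = conditionMessage(e)), blank)
  })
  res
}

#' Run a simulated benchmark grid
#'
#' Enumerates the plan of `config`, simulates reads for every experiment
#' from `reference` using each dataset's error profile, and executes each
#' cell with [run_experiment()]. Fully reproducible for a given
#' `config$seed`.
#'
#' @param config a [grid_config()]; dataset ids must name rows of
#'   `dataset_profiles`.
#' @param reference reference sequence (string); simulated regions are
#'   drawn from it.
#' @param dataset_profiles named list of [error_profile()]s, one per
#'   dataset id.
#' @param adapters named list of [tool_adapter()]s for non-builtin tools.
#' @param sc a [scoring()] object.
#' @param quiet suppress per-experiment status lines on stderr.
#' @return a `data.frame`: plan columns + `run_experiment()` columns.
#' @export
run_grid <- function(config, reference, dataset_profiles,
                     adapters = list(), sc = scoring(), quiet = TRUE) {
  plan <- enumerate_plan(config)
  set.seed(config$seed)
  regions <- sample_regions(nchar(reference), config$region_sizes,
                            config$n_regions)
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    sp <- plan[i, ]
    prof <- dataset_profiles[[sp$dataset]]
    if (is.null(prof)) stop("no error profile for dataset ", sQuote(sp$dataset))
    reg <- regions[regions$length == sp$size & regions$region == sp$region, ]
    set.seed(sp$seed)
    sim <- reads_for_region(reference, reg, sp$depth, prof)
    res <- run_experiment(sim$reads, region_template(reference, reg),
                          sp$tool, config$threshold, adapters, sc)
    if (!quiet)
      message(sprintf("[%s] size=%d region=%d depth=%d tool=%s: %s",
                      sp$dataset, sp$size, sp$region, sp$depth, sp$tool,
                      res$status))
    rows[[i]] <- cbind(sp, res, row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Summarise a grid run
#'
#' For each tool and dataset, averages the identity rate over the regions
#' of every (size, depth) combination, then reports the lowest and highest
#' of those per-combination means (the worst-case and best-case
#' combinations), plus the full per-combination mean/sd table.
#'
#' @param results a [run_grid()] result (or compatible `data.frame` with
#'   `dataset`, `size`, `region`, `depth`, `tool`, `status`,
#'   `identity_rate`).
#' @return a list with `minmax` (per tool x dataset) and `by_combination`
#'   (per tool x dataset x size x depth mean/sd of all metrics).
#' @export
summarize_grid <- function(results) {
  ok <- results[results$status == "OK", , drop = FALSE]
  if (nrow(ok) == 0L) stop("all experiments failed or were skipped")
  key <- interaction(ok$dataset, ok$tool, ok$size, ok$depth, drop = TRUE)
  pieces <- split(ok, key)
  by_comb <- do.call(rbind, lapply(pieces, function(d) {
    data.frame(dataset = d$dataset[1], tool = d$tool[1], size = d$size[1],
               depth = d$depth[1], n = nrow(d),
               mean_identity = mean(d$identity_rate),
               sd_identity = sqrt(mean((d$identity_rate -
                                        mean(d$identity_rate))^2)),
               mean_match = mean(d$match_rate),
               mean_ambiguous = mean(d$ambiguous_rate),
               mean_error = mean(d$error_rate),
               mean_size = mean(d$consensus_size))
  }))
  rownames(by_comb) <- NULL
  key2 <- interaction(by_comb$dataset, by_comb$tool, drop = TRUE)
  minmax <- do.call(rbind, lapply(split(by_comb, key2), function(d) {
    data.frame(dataset = d$dataset[1], tool = d$tool[1],
               min_identity = min(d$mean_identity),
               max_identity = max(d$mean_identity))
  }))
  rownames(minmax) <- NULL
  list(minmax = minmax, by_combination = by_comb)
}

#' Compare a metaconsensus with the best and worst per-tool consensus
#'
#' Per region, finds the best and worst per-tool identity rates and
#' tallies how often the metaconsensus is superior (`>`), equal (`=`) or
#' inferior (`<`) to each, together with the mean identity difference
#' (delta average). Equality uses identities rounded to `digits` decimals.
#'
#' @param tool_results `data.frame` with columns `region`, `tool`,
#'   `identity_rate` (one row per region x tool).
#' @param meta_results `data.frame` with columns `region`,
#'   `identity_rate` (one row per region).
#' @param digits rounding used for the equality tally (default 4).
#' @return a `data.frame` with rows `best` and `worst`: counts `gt`,
#'   `eq`, `lt` and `delta_avg`.
#' @export
compare_metaconsensus <- function(tool_results, meta_results, digits = 4L) {
  regions <- sort(unique(tool_results$region))
  if (!setequal(regions, meta_results$region))
    stop("tool and metaconsensus results cover different region sets")
  meta <- meta_results$identity_rate[match(regions, meta_results$region)]
  best <- worst <- numeric(length(regions))
  for (k in seq_along(regions)) {
    ids <- tool_results$identity_rate[tool_results$region == regions[k]]
    best[k] <- max(ids)
    worst[k] <- min(ids)
  }
  tally <- function(ref) {
    m <- round(meta, digits)
    r <- round(ref, digits)
    data.frame(gt = sum(m > r), eq = sum(m == r), lt = sum(m < r),
               delta_avg = mean(meta - ref))
  }
  out <- rbind(tally(best), tally(worst))
  out <- cbind(data.frame(versus = c("best", "worst")), out)
  out
}

#' Read a key-value benchmark config file
#'
#' Parses a minimal YAML-style `key: value` text file (comments with `#`,
#' comma-separated lists) into the arguments of [grid_config()] plus
#' optional `scoring_*` overrides.
#'
#' @param path config file path.
#' @return a list with `config` (a [grid_config()]) and `sc`
#'   (a [scoring()]).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = ":"))
    items <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(items))
    kv[[key]] <- if (!anyNA(nums)) nums else items
  }
  take <- function(name, default) if (name %in% names(kv)) kv[[name]] else default
  cfg <- grid_config(
    datasets = take("datasets", "simulated"),
    region_sizes = take("region_sizes", c(100, 200, 500, 1000, 2000, 5000,
                                          10000)),
    depths = take("depths", c(10, 20, 30, 45, 50, 60, 100, 150, 200)),
    n_regions = take("n_regions", 10L),
    tools = take("tools", "builtin"),
    threshold = take("threshold", 0.7),
    seed = take("seed", 1L)
  )
  sc <- scoring(match = take("scoring_match", 2),
                compatible = take("scoring_compatible", 1),
                mismatch = take("scoring_mismatch", -1),
                gap = take("scoring_gap", -2))
  list(config = cfg, sc = sc)
}
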