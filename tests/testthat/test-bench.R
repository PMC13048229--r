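test_that("enumerate_plan reproduces the grid combinatorics", {
  cfg <- grid_config(datasets = sprintf("d%d", 1:4),
                     tools = sprintf("tool%d", 1:9))
  plan <- enumerate_plan(cfg)
  expect_equal(nrow(plan), 22680)  # 4 x 7 x 9 x 10 x 9
  expect_equal(nrow(unique(plan[c("dataset", "size", "region", "depth",
                                  "tool")])), 22680)
  # dataset-major ordering
  expect_equal(plan$dataset[1], "d1")
  expect_equal(unique(plan$dataset), sprintf("d%d", 1:4))
  expect_true(all(plan$seed >= 0 & plan$seed < .Machine$integer.max))

  tiny <- enumerate_plan(grid_config(datasets = "d", region_sizes = 100,
                                     depths = 10, n_regions = 1,
                                     tools = "builtin"))
  expect_equal(nrow(tiny), 1)
})

test_that("plan length is the product of dimension sizes (property)", {
  set.seed(17)
  for (rep in 1:10) {
    nd <- sample(1:4, 1); ns <- sample(1:5, 1); ndep <- sample(1:4, 1)
    nr <- sample(1:6, 1); nt <- sample(1:5, 1)
    cfg <- grid_config(datasets = sprintf("d%d", 1:nd),
                       region_sizes = sample(100:1000, ns),
                       depths = sample(5:50, ndep),
                       n_regions = nr,
                       tools = sprintf("t%d", 1:nt))
    expect_equal(nrow(enumerate_plan(cfg)), nd * ns * ndep * nr * nt)
  }
})

test_that("the simulated-dataset plan covers 4 types x 8 rates", {
  cfgs <- simulated_dataset_configs()
  expect_equal(nrow(cfgs), 32)
  expect_setequal(unique(cfgs$kind), c("DEL", "INS", "SUB", "MIX"))
  expect_setequal(unique(cfgs$rate),
                  c(0.01, 0.02, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30))
  expect_equal(anyDuplicated(cfgs$dataset), 0L)
})

test_that("run_experiment: zero-error builtin pipeline reaches identity 1", {
  set.seed(33)
  ref <- random_seq(300)
  reg <- list(start = 20, length = 150)
  sim <- reads_for_region(ref, reg, 10, make_profile("MIX", 0))
  res <- run_experiment(sim$reads, substr(ref, 21, 170), tool = "builtin",
                        threshold = 0.7)
  expect_equal(res$status, "OK")
  expect_equal(res$identity_rate, 1)
  expect_equal(res$error_rate, 0)
})

test_that("adapters: conservation is enforced, missing binaries skip", {
  set.seed(34)
  reads <- stats::setNames(rep(random_seq(30), 4), sprintf("r%d", 1:4))

  identity_adapter <- tool_adapter("copy", "cp {input} {output}")
  m <- run_adapter(identity_adapter, reads)
  expect_s3_class(m, "msab_msa")
  expect_identical(sort(gsub("-", "", m$rows)), sort(unname(reads)))

  dropper <- tool_adapter("dropper", "head -n 2 {input} > {output}")
  expect_error(run_adapter(dropper, reads), "row conservation")
  res <- run_experiment(reads, reads[[1]], tool = "dropper",
                        adapters = list(dropper = dropper))
  expect_equal(res$status, "FAILED")
  expect_match(res$reason, "row conservation")

  ghost <- tool_adapter("ghost", "no_such_binary_msab {input} {output}")
  res2 <- run_experiment(reads, reads[[1]], tool = "ghost",
                         adapters = list(ghost = ghost))
  expect_equal(res2$status, "SKIPPED")
})

test_that("run_grid is reproducible and summarize_grid matches recounts", {
  cfg <- grid_config(datasets = c("MIX_5", "SUB_5"),
                     region_sizes = c(60, 120), depths = c(5, 8),
                     n_regions = 3, tools = "builtin", threshold = 0.7,
                     seed = 99L)
  set.seed(99)
  ref <- random_reference(500)
  profs <- list(MIX_5 = make_profile("MIX", 0.05),
                SUB_5 = make_profile("SUB", 0.05))
  r1 <- run_grid(cfg, ref, profs)
  r2 <- run_grid(cfg, ref, profs)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2 * 2 * 2 * 3)
  expect_true(all(r1$status == "OK"))

  s <- summarize_grid(r1)
  # independent recount of one combination
  sub <- r1[r1$dataset == "MIX_5" & r1$size == 60 & r1$depth == 8, ]
  got <- s$by_combination
  row <- got[got$dataset == "MIX_5" & got$size == 60 & got$depth == 8, ]
  expect_equal(row$mean_identity, mean(sub$identity_rate))
  expect_equal(row$n, 3)
  mm <- s$minmax[s$minmax$dataset == "MIX_5", ]
  means <- got$mean_identity[got$dataset == "MIX_5"]
  expect_equal(mm$min_identity, min(means))
  expect_equal(mm$max_identity, max(means))
})

test_that("compare_metaconsensus tallies >/=/< against best and worst", {
  tool_res <- expand.grid(region = 1:5, tool = c("t1", "t2", "t3"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tool_res$identity_rate <- c(0.90, 0.91, 0.92, 0.93, 0.94,   # t1
                              0.80, 0.81, 0.82, 0.83, 0.84,   # t2
                              0.95, 0.96, 0.97, 0.98, 0.99)   # t3
  # meta strictly between best and worst everywhere
  meta <- data.frame(region = 1:5, identity_rate = c(0.92, 0.93, 0.94,
                                                     0.95, 0.96))
  cmp <- compare_metaconsensus(tool_res, meta)
  best <- cmp[cmp$versus == "best", ]
  worst <- cmp[cmp$versus == "worst", ]
  expect_equal(c(best$gt, best$eq, best$lt), c(0, 0, 5))
  expect_equal(c(worst$gt, worst$eq, worst$lt), c(5, 0, 0))
  expect_equal(best$delta_avg, mean(c(0.92, 0.93, 0.94, 0.95, 0.96) -
                                    c(0.95, 0.96, 0.97, 0.98, 0.99)))

  # meta identical to every tool: all '='
  flat <- tool_res
  flat$identity_rate <- 0.9
  meta_eq <- data.frame(region = 1:5, identity_rate = 0.9)
  cmp_eq <- compare_metaconsensus(flat, meta_eq)
  expect_true(all(cmp_eq$eq == 5))
  expect_true(all(cmp_eq$delta_avg == 0))

  # randomized identities: tallies match a brute-force recount
  set.seed(61)
  rnd <- tool_res
  rnd$identity_rate <- round(runif(nrow(rnd), 0.8, 1), 3)
  meta_r <- data.frame(region = 1:5,
                       identity_rate = round(runif(5, 0.8, 1), 3))
  cmp_r <- compare_metaconsensus(rnd, meta_r)
  for (vs in c("best", "worst")) {
    pick <- if (vs == "best") max else min
    refv <- vapply(1:5, function(r)
      pick(rnd$identity_rate[rnd$region == r]), numeric(1))
    mv <- meta_r$identity_rate
    row <- cmp_r[cmp_r$versus == vs, ]
    expect_equal(row$gt, sum(round(mv, 4) > round(refv, 4)))
    expect_equal(row$eq, sum(round(mv, 4) == round(refv, 4)))
    expect_equal(row$lt, sum(round(mv, 4) < round(refv, 4)))
    expect_equal(row$delta_avg, mean(mv - refv))
  }

  expect_error(compare_metaconsensus(tool_res,
                                     data.frame(region = 1:4,
                                                identity_rate = 0.9)),
               "different region sets")
})

test_that("config files parse into grid and scoring settings", {
  cfgfile <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# benchmark config",
               "datasets: MIX_10, SUB_5",
               "region_sizes: 100, 200",
               "depths: 10, 20",
               "n_regions: 3",
               "tools: builtin",
               "threshold: 0.7",
               "seed: 5",
               "scoring_gap: -3"), cfgfile)
  parsed <- read_config(cfgfile)
  expect_equal(parsed$config$datasets, c("MIX_10", "SUB_5"))
  expect_equal(parsed$config$region_sizes, c(100L, 200L))
  expect_equal(parsed$config$n_regions, 3L)
  expect_equal(parsed$config$seed, 5L)
  expect_equal(parsed$sc$gap, -3L)
  expect_equal(parsed$sc$match, 2L)
})

test_that("the CLI round-trips simulate -> msa -> consensus -> evaluate", {
  dir <- withr::local_tempdir()
  ref <- withr::local_tempfile(fileext = ".fasta")
  set.seed(71)
  write_fasta(c(ref = random_seq(200)), ref)
  out <- file.path(dir, "sim")
  msabench_cli(c("simulate-reads", "--reference", ref, "--profile", "MIX",
                 "--rate", "0", "--start", "20", "--length", "80",
                 "--depth", "6", "--seed", "4", "--out", out))
  expect_true(file.exists(paste0(out, ".fasta")))
  expect_true(file.exists(paste0(out, ".truth.tsv")))

  out2 <- file.path(dir, "aln")
  msabench_cli(c("msa", "--reads", paste0(out, ".fasta"), "--out", out2))
  out3 <- file.path(dir, "cons")
  msabench_cli(c("consensus", "--msa", paste0(out2, ".afa"),
                 "--threshold", "0.7", "--out", out3))
  out4 <- file.path(dir, "eval")
  msabench_cli(c("evaluate", "--consensus", paste0(out3, ".fasta"),
                 "--reference", ref, "--out", out4))
  met <- utils::read.table(paste0(out4, ".metrics.tsv"), header = TRUE,
                           sep = "\t")
  # zero-error reads over a window: consensus matches that window exactly
  expect_equal(met$identity_rate, 1)
  expect_equal(met$consensus_size, 80)
})
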