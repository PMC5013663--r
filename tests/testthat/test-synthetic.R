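test_that("generation is deterministic given the seed", {
  cfg <- scenario_config(seed = 99, n_blocks = 2, n_training_sites = 2,
                         n_rounds = 2, n_host_taxa = 8,
                         n_parasitoid_taxa = 5, connectance = 0.25)
  a <- generate_scenario(cfg)
  b <- generate_scenario(cfg)
  expect_identical(a$training, b$training)
  expect_identical(a$validation, b$validation)
  expect_identical(a$truth$d_true, b$truth$d_true)
  # and the CSV serialization is byte-identical
  fa <- tempfile(fileext = ".csv")
  fb <- tempfile(fileext = ".csv")
  write_rearing_records(a$validation, fa)
  write_rearing_records(b$validation, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("generated records satisfy every ingest invariant", {
  scen <- generate_scenario(scenario_config(
    seed = 13, n_blocks = 2, n_host_taxa = 10, n_parasitoid_taxa = 6,
    connectance = 0.2))
  # as_rearing_records re-validates from scratch; round-tripping through
  # CSV exercises the parser too
  f <- tempfile(fileext = ".csv")
  write_rearing_records(scen$training, f)
  expect_s3_class(read_rearing_records(f), "rearing_records")
  expect_true(all(scen$validation$timestep %in% c("before", "after")))
  expect_true(all(!is.na(scen$training$round)))
  # one reduction site per block
  tab <- table(scen$design$block_id, scen$design$treatment)
  expect_true(all(tab[, "reduction"] == 1))
})

test_that("true dependence rows sum to one for parasitized hosts", {
  scen <- generate_scenario(scenario_config(
    seed = 17, n_blocks = 2, n_host_taxa = 12, n_parasitoid_taxa = 8,
    connectance = 0.15))
  d <- scen$truth$d_true
  linked <- rowSums(scen$truth$affinity) > 0
  expect_lt(max(abs(rowSums(d)[linked] - 1)), 1e-10)
  expect_true(all(rowSums(d)[!linked] == 0))
})

test_that("the empirical dependence converges to the truth with more rounds", {
  err_for <- function(rounds, seed) {
    scen <- generate_scenario(scenario_config(
      seed = seed, n_blocks = 2, n_training_sites = 8, n_rounds = rounds,
      n_host_taxa = 8, n_parasitoid_taxa = 5, connectance = 0.3,
      abund_mean = c(P = 12, N = 8)))
    mw <- build_web(scen$training, dataset = "training")
    dep <- dependence_matrix(mw)
    truth <- scen$truth$d_true
    common <- intersect(rownames(dep$values), rownames(truth))
    # compare over hosts parasitized in the sample
    par <- common[dep$parasitized[match(common, dep$hosts$key)]]
    max(abs(dep$values[par, common] - truth[par, common]))
  }
  errs_small <- vapply(1:3, function(s) err_for(4, 3000 + s), 0)
  errs_large <- vapply(1:3, function(s) err_for(40, 3000 + s), 0)
  expect_lt(mean(errs_large), mean(errs_small))
})

test_that("deterministic mode realizes the configured arithmetic exactly", {
  # treated plantation host with n(t) = 10 and reduction 0.3 ends at 3
  cfg <- scenario_config(seed = 1, n_blocks = 1, n_training_sites = 1,
                         n_rounds = 1, n_host_taxa = 6,
                         n_parasitoid_taxa = 6, habitat_overlap = 0.5,
                         connectance = 1 / 6, abund_mean = c(P = 10, N = 10),
                         p_base = 0.1, rearing_success = 1,
                         extra_fraction = 0, reduction_factor = 0.3,
                         decline_factor = 0.8)
  scen <- deterministic_scenario(cfg)
  panels <- site_panels(scen$validation, scen$design)
  treated <- panels[[which(scen$design$treatment == "reduction")[1]]]
  p_hosts <- treated$data[treated$data$habitat == "P", ]
  expect_true(all(p_hosts$n_total_t == 10L))
  expect_true(all(p_hosts$n_total_t1 == 3L))
  n_hosts <- treated$data[treated$data$habitat == "N", ]
  expect_true(all(n_hosts$n_total_t1 == 8L))
  # the abundance change equals the configured decline exactly
  expect_true(all(abundance_change(treated)[p_hosts$key] == -7))
})

test_that("non-integral expectations are refused with the offending quantity", {
  cfg <- scenario_config(seed = 1, n_blocks = 1, n_host_taxa = 6,
                         n_parasitoid_taxa = 6, connectance = 1 / 6,
                         abund_mean = c(P = 10, N = 10), p_base = 0.13,
                         rearing_success = 1, extra_fraction = 0)
  expect_error(deterministic_scenario(cfg), "n \\* p_base")
  cfg2 <- scenario_config(seed = 1, n_blocks = 1, n_host_taxa = 6,
                          n_parasitoid_taxa = 6, connectance = 1 / 6,
                          abund_mean = c(P = 10, N = 10), p_base = 0.1,
                          rearing_success = 1, extra_fraction = 0.15)
  expect_error(deterministic_scenario(cfg2), "extra_fraction")
})

test_that("deterministic lambda = 1 round trip: pipeline E equals the truth", {
  scen <- deterministic_scenario(det_config(seed = 5, n_blocks = 2))
  mw <- build_web(scen$training, dataset = "training")
  dep <- dependence_matrix(mw)
  panels <- site_panels(scen$validation, scen$design)
  tab <- assemble_prediction_table(dep, panels, quiet = TRUE)
  truth <- scen$truth$rates
  m <- merge(tab[tab$included, ],
             truth, by.x = c("site_id", "host_taxon", "habitat"),
             by.y = c("site_id", "host_taxon", "habitat"))
  expect_gt(nrow(m), 0)
  expect_lt(max(abs(m$E - m$rate)), 1e-12)
})

test_that("lambda = 0 decouples later parasitism from abundance changes", {
  # with no coupling the true t+1 rate is flat at the baseline
  scen <- generate_scenario(scenario_config(
    seed = 23, n_blocks = 2, n_host_taxa = 10, n_parasitoid_taxa = 6,
    connectance = 0.2, lambda = 0))
  linked <- names(which(rowSums(scen$truth$affinity) > 0))
  r <- scen$truth$rates
  # linked hosts present at t+1 sit exactly at the baseline; unlinked or
  # absent hosts at zero
  expect_true(all(r$rate %in% c(0, scen$truth$config$p_base)))
  expect_true(any(r$rate[r$key %in% linked] ==
                    scen$truth$config$p_base))
  expect_true(all(r$rate[!r$key %in% linked] == 0))
})
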