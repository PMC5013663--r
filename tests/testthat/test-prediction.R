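toy_dep <- function() {
  # 3-host web: W1 shared by A|P and B|N, W2 exclusive to C|P
  counts <- matrix(c(2L, 2L, 0L,
                     0L, 0L, 3L), 3, 2)
  web <- quantweb(counts,
                  data.frame(taxon = c("A", "B", "C"),
                             habitat = c("P", "N", "P")),
                  c("W1", "W2"))
  dependence_matrix(web)
}

toy_panel <- function(...) {
  defaults <- data.frame(
    host_taxon = c("A", "B", "C"), habitat = c("P", "N", "P"),
    n_transect_t = c(10L, 8L, 6L), n_transect_t1 = c(5L, 16L, 6L),
    n_total_t = c(12L, 10L, 8L), n_total_t1 = c(6L, 18L, 8L),
    reared_t = c(6L, 5L, 4L), reared_t1 = c(3L, 9L, 4L),
    attacks_t = c(3L, 2L, 2L), attacks_t1 = c(1L, 4L, 1L),
    stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  site_panel(defaults, site_id = "V01", block_id = "B01",
             treatment = "control")
}

test_that("expected rates match term-by-term enumeration on a toy panel", {
  dep <- toy_dep()
  panel <- toy_panel()
  res <- expected_parasitism(dep, panel)
  for (k in res$key) {
    expect_equal(res$E_raw[res$key == k],
                 oracle_expected_one(dep, panel, k), tolerance = 1e-15)
  }
  # and the explicit hand value for focal A|P:
  # d(A,A)=0.5, d(A,B)=0.5; terms (3/10)*5*0.5 + (3/8)*16*0.5, over 6
  expect_equal(res$E_raw[res$key == "A|P"],
               (0.5 * (3 / 10) * 5 + 0.5 * (3 / 8) * 16) / 6)
})

test_that("constant abundances collapse the expected rate to the initial rate", {
  for (i in 1:10) {
    web <- random_quantweb(n_hosts = 10, n_parasitoids = 6, seed = 300 + i)
    dep <- dependence_matrix(web)
    panel <- random_site_panel(dep, equal_abundance = TRUE, seed = 400 + i)
    e <- expected_parasitism(dep, panel)
    ini <- initial_parasitism(panel)
    ok <- e$included & dep$parasitized[match(e$key, dep$hosts$key)]
    expect_gt(sum(ok), 0)
    expect_lt(max(abs(e$E_raw[ok] - ini[e$key[ok]])), 1e-12)
  }
})

test_that("the expected rate is linear in each partner's later abundance", {
  dep <- toy_dep()
  p1 <- toy_panel()
  p2 <- toy_panel(n_transect_t1 = c(5L, 32L, 6L),
                  n_total_t1 = c(6L, 34L, 8L))
  e1 <- expected_parasitism(dep, p1)
  e2 <- expected_parasitism(dep, p2)
  # focal A|P shares only with B|N (and itself); doubling B's t+1 abundance
  # doubles B's contribution to E_raw
  contrib1 <- e1$E_raw[e1$key == "A|P"] - 0.5 * (3 / 10) * 5 / 6
  contrib2 <- e2$E_raw[e2$key == "A|P"] - 0.5 * (3 / 10) * 5 / 6
  expect_equal(contrib2, 2 * contrib1, tolerance = 1e-12)
})

test_that("rates above one are clipped while the raw value is retained", {
  dep <- toy_dep()
  panel <- toy_panel(n_transect_t1 = c(2L, 80L, 6L),
                     n_total_t1 = c(2L, 82L, 8L),
                     reared_t1 = c(2L, 9L, 4L), attacks_t1 = c(1L, 4L, 1L))
  e <- expected_parasitism(dep, panel)
  row <- e[e$key == "A|P", ]
  expect_gt(row$E_raw, 1)
  expect_equal(row$E, 1)
})

test_that("within and cross components add to the raw rate", {
  for (i in 1:20) {
    web <- random_quantweb(n_hosts = 12, n_parasitoids = 7, seed = 500 + i)
    dep <- dependence_matrix(web)
    panel <- random_site_panel(dep, seed = 600 + i)
    e <- expected_parasitism(dep, panel)
    ok <- e$included
    expect_lt(max(abs(e$E_within[ok] + e$E_cross[ok] - e$E_raw[ok])), 1e-12)
    expect_true(all(e$E[ok] <= 1 + 1e-15))
    expect_true(all(e$E_raw[ok] >= e$E[ok] - 1e-15))
    # scope restriction agrees with the component columns
    eo <- expected_parasitism(dep, panel, scope = "own")
    ec <- expected_parasitism(dep, panel, scope = "cross")
    expect_equal(eo$E_raw, e$E_within, tolerance = 1e-12)
    expect_equal(ec$E_raw, e$E_cross, tolerance = 1e-12)
  }
})

test_that("hosts sharing parasitoids only within their habitat have zero cross rate", {
  # single-habitat web: no cross-habitat partners exist
  web <- random_quantweb(n_hosts = 6, n_parasitoids = 4, habitats = "P",
                         seed = 9)
  dep <- dependence_matrix(web)
  panel <- random_site_panel(dep, seed = 10)
  e <- expected_parasitism(dep, panel)
  expect_true(all(e$E_cross == 0))
})

test_that("a focal with one cross-habitat partner gets exactly that term", {
  dep <- toy_dep()
  panel <- toy_panel()
  e <- expected_parasitism(dep, panel)
  row <- e[e$key == "B|N", ]
  # B|N's only cross partner is A|P: d(B,A) * (attacks_B(t)/n_A(t)) * n_A(t+1)
  expect_equal(row$E_cross, 0.5 * (2 / 10) * 5 / 18, tolerance = 1e-15)
})

test_that("intraspecific exclusion removes only same-habitat self terms", {
  # the same taxon in both habitats: the cross-habitat self term stays
  counts <- matrix(c(2L, 2L), 2, 1)
  web <- quantweb(counts, data.frame(taxon = c("A", "A"),
                                     habitat = c("N", "P")), "W")
  dep <- dependence_matrix(web)
  panel <- site_panel(data.frame(
    host_taxon = c("A", "A"), habitat = c("N", "P"),
    n_transect_t = c(4L, 4L), n_transect_t1 = c(4L, 4L),
    n_total_t = c(4L, 4L), n_total_t1 = c(4L, 4L),
    reared_t = c(4L, 4L), reared_t1 = c(4L, 4L),
    attacks_t = c(2L, 2L), attacks_t1 = c(1L, 1L)),
    site_id = "V01", block_id = "B01", treatment = "control")
  full <- expected_parasitism(dep, panel)
  noself <- expected_parasitism(dep, panel,
                                exclude_within_intraspecific = TRUE)
  # both halves are self-terms at taxon level, but only the same-habitat
  # one is removed; each contributes half of E_raw here
  expect_equal(noself$E_raw, full$E_raw / 2, tolerance = 1e-12)
  expect_equal(full$E_noself, noself$E)
})

test_that("observed, initial and abundance-change follow their definitions", {
  panel <- toy_panel(attacks_t1 = c(3L, 0L, 1L), reared_t1 = c(3L, 9L, 4L),
                     n_total_t1 = c(10L, 18L, 8L),
                     n_transect_t = c(12L, 8L, 6L),
                     n_total_t = c(12L, 10L, 8L),
                     n_transect_t1 = c(4L, 16L, 6L))
  o <- observed_parasitism(panel)
  expect_equal(unname(o["A|P"]), 0.3)
  expect_equal(unname(o["B|N"]), 0)
  i <- initial_parasitism(panel)
  expect_equal(unname(i["B|N"]), 2 / 10)
  dn <- abundance_change(panel)
  expect_equal(unname(dn["A|P"]), -8)
})

test_that("a host absent on both occasions changes by zero", {
  panel <- toy_panel(n_transect_t = c(0L, 8L, 6L),
                     n_transect_t1 = c(0L, 16L, 6L),
                     n_total_t = c(0L, 10L, 8L), n_total_t1 = c(0L, 18L, 8L),
                     reared_t = c(0L, 5L, 4L), reared_t1 = c(0L, 9L, 4L),
                     attacks_t = c(0L, 2L, 2L), attacks_t1 = c(0L, 4L, 1L))
  expect_equal(unname(abundance_change(panel)["A|P"]), 0)
})

test_that("prediction rows carry inclusion flags with reasons", {
  dep <- toy_dep()
  panel <- toy_panel(n_total_t1 = c(6L, 18L, 0L), n_transect_t1 = c(5L, 16L, 0L),
                     reared_t1 = c(3L, 9L, 0L), attacks_t1 = c(1L, 4L, 0L))
  tab <- assemble_prediction_table(dep, panel, quiet = TRUE)
  expect_s3_class(tab, "prediction_table")
  expect_true(tab$included[tab$host_taxon == "A"])
  expect_equal(tab$exclusion_reason[tab$host_taxon == "C"], "absent at t+1")
  # unparasitized at t
  p2 <- toy_panel(attacks_t = c(0L, 2L, 2L))
  t2 <- assemble_prediction_table(dep, p2, quiet = TRUE)
  expect_equal(t2$exclusion_reason[t2$host_taxon == "A"],
               "unparasitized at t")
  # partners absent from the training web contribute d = 0: an extra host
  # in the panel does not change E of the others
  extra <- rbind(panel$data[names(panel$data) != "key"],
                 data.frame(host_taxon = "Z", habitat = "P",
                            n_transect_t = 5L, n_transect_t1 = 5L,
                            n_total_t = 5L, n_total_t1 = 5L,
                            reared_t = 2L, reared_t1 = 2L,
                            attacks_t = 1L, attacks_t1 = 0L))
  p3 <- site_panel(extra, "V01", "B01", "control")
  t3 <- assemble_prediction_table(dep, p3, quiet = TRUE)
  expect_equal(t3$E[t3$host_taxon == "A"], tab$E[tab$host_taxon == "A"],
               tolerance = 1e-15)
  expect_equal(t3$E[t3$host_taxon == "Z"], 0)
})
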