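# Independent reference implementations used to check the vectorized code,
# plus small record constructors.

# Naive triple-loop Muller dependence: loops over (focal, source,
# parasitoid) with explicit 0/0 guards. `pool` is a logical over hosts
# marking the parasitoid-pool membership (source columns).
oracle_dependence <- function(counts, pool = rep(TRUE, nrow(counts))) {
  H <- nrow(counts)
  P <- ncol(counts)
  src <- which(pool)
  d <- matrix(0, H, length(src))
  for (i in seq_len(H)) {
    tot_i <- sum(counts[i, ])
    if (tot_i == 0) next
    for (jj in seq_along(src)) {
      j <- src[jj]
      acc <- 0
      for (k in seq_len(P)) {
        pool_k <- sum(counts[src, k])
        if (pool_k > 0) {
          acc <- acc + (counts[i, k] / tot_i) * (counts[j, k] / pool_k)
        }
      }
      d[i, jj] <- acc
    }
  }
  dimnames(d) <- list(rownames(counts), rownames(counts)[src])
  d
}

# Term-by-term expected-rate evaluation: explicit loop over partners for
# one focal host, mirroring the spreadsheet-style enumeration.
oracle_expected_one <- function(dep, panel, focal_key,
                                scope = "both",
                                exclude_within_intraspecific = FALSE) {
  d <- panel$data
  f <- d[d$key == focal_key, ]
  if (f$n_total_t1 == 0) return(NA_real_)
  total <- 0
  for (j in seq_len(nrow(d))) {
    if (d$n_transect_t[j] == 0) next
    if (scope == "own" && d$habitat[j] != f$habitat) next
    if (scope == "cross" && d$habitat[j] == f$habitat) next
    if (exclude_within_intraspecific &&
        d$host_taxon[j] == f$host_taxon && d$habitat[j] == f$habitat) next
    ri <- match(focal_key, dep$hosts$key)
    cj <- match(d$key[j], dep$sources$key)
    dv <- if (is.na(ri) || is.na(cj)) 0 else dep$values[ri, cj]
    total <- total + dv * (f$attacks_t / d$n_transect_t[j]) *
      d$n_transect_t1[j]
  }
  total / f$n_total_t1
}

# Quick record constructor with sensible defaults.
make_records <- function(host, habitat, parasitoid = NA_character_,
                         reared = TRUE, dataset = "training",
                         site = "T01", block = "B01", round = 1L,
                         timestep = NA_character_, source = "transect",
                         id = NULL) {
  n <- max(length(host), length(habitat), length(parasitoid),
           length(reared), length(site), length(timestep), length(source))
  as_rearing_records(data.frame(
    record_id = id %||% sprintf("R%04d", seq_len(n)),
    dataset = rep_len(dataset, n), site_id = rep_len(site, n),
    block_id = rep_len(block, n), round = rep_len(round, n),
    timestep = rep_len(timestep, n), habitat = rep_len(habitat, n),
    source = rep_len(source, n), host_taxon = rep_len(host, n),
    reared_ok = rep_len(reared, n),
    parasitoid_taxon = rep_len(parasitoid, n), stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic-mode configuration with all expectations integral.
det_config <- function(seed = 1, n_blocks = 2, lambda = 1, ...) {
  scenario_config(seed = seed, n_blocks = n_blocks,
                  n_training_sites = 4, n_rounds = 3,
                  n_host_taxa = 8, n_parasitoid_taxa = 6,
                  habitat_overlap = 0.5, connectance = 1 / 3,
                  abund_mean = c(P = 20, N = 20), p_base = 0.2,
                  rearing_success = 1, extra_fraction = 0.5,
                  reduction_factor = 0.3, decline_factor = 0.5,
                  lambda = lambda, ...)
}

# Synthetic dependence_matrix with prescribed positive values, for the
# habitat-pair ANOVA tests.
fake_dependence <- function(values, habitats_i, habitats_j) {
  hosts <- data.frame(taxon = sprintf("H%03d", seq_along(habitats_i)),
                      habitat = habitats_i)
  hosts$key <- paste(hosts$taxon, hosts$habitat, sep = "|")
  sources <- data.frame(taxon = sprintf("S%03d", seq_along(habitats_j)),
                        habitat = habitats_j)
  sources$key <- paste(sources$taxon, sources$habitat, sep = "|")
  structure(list(values = values, hosts = hosts, sources = sources,
                 pool_scope = c("N", "P"), basis = "quantitative",
                 parasitized = rep(TRUE, nrow(values))),
            class = "dependence_matrix")
}
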