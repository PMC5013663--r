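#' Scenario configuration for the synthetic community
#'
#' Describes the simulated study: a regional training design (sites x
#' sampling rounds) for the metaweb, and a blocked BACI validation design
#' (two sites per block, two habitats, two timesteps) with an
#' herbivore-reduction treatment applied to the plantation side of one site
#' per block between timesteps.
#'
#' Defaults mirror the field design: 8 spatial blocks, 8 training sites, 7
#' sampling rounds, a web connectance target of 0.057, plantation abundance
#' above native abundance (higher plantation productivity), a reduction
#' factor of 0.3 on treated plantations, a natural between-timestep decline
#' (wasp-predation effect) elsewhere, and a rearing success probability of
#' 0.33. Taxon richness defaults are scaled below the field community so
#' simulation sweeps stay cheap; the full-scale community (70 host and 46
#' parasitoid taxa) can be requested explicitly.
#'
#' @param seed Mandatory integer seed; expanded internally into per-stage
#'   child seeds so stages can be varied independently.
#' @param n_blocks Spatial blocks (each: one reduction + one control site).
#' @param n_training_sites,n_rounds Regional metaweb design.
#' @param n_host_taxa,n_parasitoid_taxa Community richness.
#' @param habitat_overlap Fraction of host taxa occurring in both habitats.
#' @param connectance Target binary connectance of the affinity web.
#' @param abund_mean Named vector `c(P = , N = )` of mean per-host
#'   collected abundance per site and timestep (or per site and round, for
#'   training).
#' @param abund_size Negative-binomial dispersion (size) parameter.
#' @param p_base Baseline per-capita parasitism probability of hosts with
#'   at least one parasitoid link.
#' @param rearing_success Probability a collected individual is reared to
#'   moth or parasitoid emergence (independent of parasitism status).
#' @param reduction_factor Multiplier on treated-plantation abundance at
#'   `t+1` (the spray effect), in `(0, 1]`.
#' @param decline_factor Natural between-timestep abundance multiplier for
#'   untreated panels.
#' @param lambda Apparent-competition coupling in `[-1, 1]`: at 1 the
#'   `t+1` parasitism rate is exactly the shared-parasitoid expectation; at
#'   0 it is independent of partner abundance changes; negative values
#'   invert the abundance-change effect (apparent mutualism).
#' @param extra_fraction Fraction of collected individuals labelled as
#'   extra (non-transect) sampling.
#' @param affinity_sdlog Log-normal sd of affinity link weights.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(seed,
                            n_blocks = 8,
                            n_training_sites = 8,
                            n_rounds = 7,
                            n_host_taxa = 30,
                            n_parasitoid_taxa = 20,
                            habitat_overlap = 0.5,
                            connectance = 0.057,
                            abund_mean = c(P = 6, N = 4),
                            abund_size = 1.5,
                            p_base = 0.13,
                            rearing_success = 0.33,
                            reduction_factor = 0.3,
                            decline_factor = 0.7,
                            lambda = 1,
                            extra_fraction = 0.15,
                            affinity_sdlog = 1) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop_edgeweb("a seed is mandatory")
  }
  cfg <- list(seed = as.integer(seed), n_blocks = n_blocks,
              n_training_sites = n_training_sites, n_rounds = n_rounds,
              n_host_taxa = n_host_taxa,
              n_parasitoid_taxa = n_parasitoid_taxa,
              habitat_overlap = habitat_overlap, connectance = connectance,
              abund_mean = abund_mean, abund_size = abund_size,
              p_base = p_base, rearing_success = rearing_success,
              reduction_factor = reduction_factor,
              decline_factor = decline_factor, lambda = lambda,
              extra_fraction = extra_fraction,
              affinity_sdlog = affinity_sdlog)
  stopifnot(cfg$lambda >= -1, cfg$lambda <= 1,
            cfg$reduction_factor > 0, cfg$reduction_factor <= 1,
            cfg$decline_factor > 0, cfg$decline_factor <= 1,
            all(cfg$abund_mean > 0), cfg$abund_size > 0,
            cfg$p_base >= 0, cfg$p_base <= 1,
            cfg$rearing_success > 0, cfg$rearing_success <= 1,
            cfg$extra_fraction >= 0, cfg$extra_fraction < 1,
            all(c("P", "N") %in% names(cfg$abund_mean)))
  class(cfg) <- "scenario_config"
  cfg
}

# Host pool: which taxa occur in which habitat(s), sorted registry.
community_hosts <- function(cfg) {
  taxa <- sprintf("H%03d", seq_len(cfg$n_host_taxa))
  n_shared <- round(cfg$habitat_overlap * cfg$n_host_taxa)
  rest <- cfg$n_host_taxa - n_shared
  p_only <- taxa[n_shared + seq_len(ceiling(rest / 2))]
  n_only <- setdiff(taxa[-seq_len(n_shared)], p_only)
  hosts <- rbind(
    data.frame(taxon = rep(taxa[seq_len(n_shared)], each = 2),
               habitat = rep(c("N", "P"), n_shared)),
    data.frame(taxon = p_only, habitat = rep("P", length(p_only))),
    data.frame(taxon = n_only, habitat = rep("N", length(n_only))))
  hosts <- hosts[order(hosts$taxon, hosts$habitat, method = "radix"), ,
                 drop = FALSE]
  hosts$key <- host_key(hosts$taxon, hosts$habitat)
  rownames(hosts) <- NULL
  hosts
}

# Sparse host x parasitoid affinity matrix hitting the connectance target.
draw_affinity <- function(cfg, hosts, deterministic = FALSE) {
  H <- nrow(hosts)
  P <- cfg$n_parasitoid_taxa
  parasitoids <- sprintf("W%03d", seq_len(P))
  A <- matrix(0, H, P, dimnames = list(hosts$key, parasitoids))
  if (deterministic) {
    deg <- max(1L, round(cfg$connectance * P))
    for (r in seq_len(H)) {
      cols <- ((r - 1) * deg + seq_len(deg) - 1) %% P + 1
      A[r, cols] <- 1
    }
  } else {
    L <- round(cfg$connectance * H * P)
    if (L < 1 || L > H * P) {
      stop_edgeweb("connectance target ", cfg$connectance,
                   " infeasible for a ", H, " x ", P, " web")
    }
    cells <- sample.int(H * P, L)
    A[cells] <- stats::rlnorm(L, meanlog = 0, sdlog = cfg$affinity_sdlog)
  }
  A
}

# Reference dependence computation: a deliberately naive triple loop over
# (focal, source, parasitoid), used for generator ground truth.
true_dependence <- function(counts) {
  H <- nrow(counts)
  P <- ncol(counts)
  d <- matrix(0, H, H, dimnames = list(rownames(counts), rownames(counts)))
  row_tot <- rowSums(counts)
  col_tot <- colSums(counts)
  for (i in seq_len(H)) {
    if (row_tot[i] == 0) next
    for (j in seq_len(H)) {
      acc <- 0
      for (k in seq_len(P)) {
        if (col_tot[k] > 0) {
          acc <- acc + (counts[i, k] / row_tot[i]) *
            (counts[j, k] / col_tot[k])
        }
      }
      d[i, j] <- acc
    }
  }
  d
}

# Eq.-style expected rates from ground-truth quantities, plain double loop.
# attacks_t, n_tr0, n_tr1, n1_total are vectors over the host registry for
# one site; lambda < 0 reflects the abundance ratio around 1.
true_rates_for_site <- function(d_true, attacks_t, n_tr0, n_tr1, n1_total,
                                p_eff, lambda) {
  H <- length(attacks_t)
  rate <- numeric(H)
  for (i in seq_len(H)) {
    if (n1_total[i] == 0) next
    expt <- 0
    for (j in seq_len(H)) {
      if (n_tr0[j] == 0) next
      r <- n_tr1[j] / n_tr0[j]
      m <- if (lambda >= 0) r else max(2 - r, 0)
      expt <- expt + d_true[i, j] * m
    }
    expt <- (attacks_t[i] / n1_total[i]) * expt
    rate[i] <- min(max((1 - abs(lambda)) * p_eff[i] + abs(lambda) * expt,
                       0), 1)
  }
  rate
}

# Draw individuals for one (site, occasion) across all hosts; returns a
# data.frame of individual-level fields plus per-host totals.
draw_occasion <- function(hosts, n, affinity, p_eff, cfg, rates = NULL) {
  idx <- rep(seq_len(nrow(hosts)), n)
  n_tot <- length(idx)
  if (n_tot == 0) {
    return(list(df = NULL, attacks = integer(nrow(hosts)),
                n_transect = integer(nrow(hosts))))
  }
  p_ind <- if (is.null(rates)) p_eff[idx] else rates[idx]
  parasitized <- stats::runif(n_tot) < p_ind
  parasitoid <- rep(NA_character_, n_tot)
  for (h in unique(idx[parasitized])) {
    sel <- which(parasitized & idx == h)
    w <- affinity[h, ]
    if (sum(w) == 0) {
      parasitized[sel] <- FALSE
      next
    }
    parasitoid[sel] <- sample(colnames(affinity), length(sel),
                              replace = TRUE, prob = w)
  }
  src <- ifelse(stats::runif(n_tot) < cfg$extra_fraction, "extra",
                "transect")
  reared <- stats::runif(n_tot) < cfg$rearing_success
  list(df = data.frame(host_row = idx, parasitized = parasitized,
                       parasitoid = parasitoid, source = src,
                       reared = reared, stringsAsFactors = FALSE),
       attacks = tabulate(idx[parasitized], nbins = nrow(hosts)),
       n_transect = tabulate(idx[src == "transect"], nbins = nrow(hosts)))
}

occasion_records <- function(occ, hosts, prefix, dataset, site_id, block_id,
                             round, timestep) {
  if (is.null(occ$df)) return(NULL)
  d <- occ$df
  data.frame(
    record_id = paste0(prefix, seq_len(nrow(d))),
    dataset = dataset, site_id = site_id, block_id = block_id,
    round = if (is.na(round)) NA_integer_ else round,
    timestep = timestep,
    habitat = hosts$habitat[d$host_row], source = d$source,
    host_taxon = hosts$taxon[d$host_row], reared_ok = d$reared,
    parasitoid_taxon = ifelse(d$parasitized & d$reared, d$parasitoid,
                              NA_character_),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic training + validation dataset
#'
#' Draws a sparse host x parasitoid affinity web at the target connectance,
#' simulates the regional training design (negative-binomial abundances,
#' binomial parasitism, multinomial parasitoid attribution, Bernoulli
#' rearing success and transect/extra labelling), and the blocked BACI
#' validation design: one site per block is sprayed (plantation abundance
#' multiplied by `reduction_factor` at `t+1`), the rest decline naturally.
#' At `t+1` the parasitism rate of each host is a `lambda`-mixture of the
#' baseline rate and the shared-parasitoid expectation computed from the
#' true dependence matrix and the realized abundance changes, so the
#' strength (and sign) of apparent competition in the data is controlled.
#'
#' @param config A [scenario_config()].
#' @return A `scenario` list: `training` and `validation` rearing records,
#'   `design` (site/block/treatment), and `truth` (affinity matrix, true
#'   dependence matrix, per-site true `t+1` rates, and the config).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  set.seed(child_seed(cfg$seed, "community"))
  hosts <- community_hosts(cfg)
  affinity <- draw_affinity(cfg, hosts)
  p_eff <- ifelse(rowSums(affinity) > 0, cfg$p_base, 0)
  mean_h <- unname(cfg$abund_mean[hosts$habitat])

  # ground-truth dependence from expected regional attack counts
  share <- affinity / ifelse(rowSums(affinity) > 0, rowSums(affinity), 1)
  C_true <- share * (mean_h * p_eff)
  d_true <- true_dependence(C_true)

  # training records
  set.seed(child_seed(cfg$seed, "training"))
  training <- vector("list", cfg$n_training_sites * cfg$n_rounds)
  k <- 0
  for (s in seq_len(cfg$n_training_sites)) {
    for (r in seq_len(cfg$n_rounds)) {
      n <- stats::rnbinom(nrow(hosts), mu = mean_h, size = cfg$abund_size)
      occ <- draw_occasion(hosts, n, affinity, p_eff, cfg)
      k <- k + 1
      training[[k]] <- occasion_records(
        occ, hosts, prefix = sprintf("T%02d%02d-", s, r),
        dataset = "training", site_id = sprintf("T%02d", s),
        block_id = "regional", round = r, timestep = NA_character_)
    }
  }
  training <- as_rearing_records(do.call(rbind, training))

  # validation design: one reduction site per block
  set.seed(child_seed(cfg$seed, "design"))
  design <- data.frame(
    site_id = sprintf("V%02d", seq_len(2 * cfg$n_blocks)),
    block_id = sprintf("B%02d", rep(seq_len(cfg$n_blocks), each = 2)),
    stringsAsFactors = FALSE)
  design$treatment <- "control"
  for (b in unique(design$block_id)) {
    rows <- which(design$block_id == b)
    design$treatment[sample(rows, 1)] <- "reduction"
  }

  set.seed(child_seed(cfg$seed, "validation"))
  validation <- list()
  truth_rates <- list()
  for (v in seq_len(nrow(design))) {
    sid <- design$site_id[v]
    treated <- design$treatment[v] == "reduction"
    n0 <- stats::rnbinom(nrow(hosts), mu = mean_h, size = cfg$abund_size)
    mult <- ifelse(treated & hosts$habitat == "P", cfg$reduction_factor,
                   cfg$decline_factor)
    n1 <- stats::rnbinom(nrow(hosts), mu = mult * mean_h,
                         size = cfg$abund_size)
    occ0 <- draw_occasion(hosts, n0, affinity, p_eff, cfg)
    # t+1 sampling labels must exist before rates (transect ratios)
    idx1 <- rep(seq_len(nrow(hosts)), n1)
    src1 <- ifelse(stats::runif(length(idx1)) < cfg$extra_fraction,
                   "extra", "transect")
    n_tr1 <- tabulate(idx1[src1 == "transect"], nbins = nrow(hosts))
    rate <- true_rates_for_site(d_true, occ0$attacks, occ0$n_transect,
                                n_tr1, n1, p_eff, cfg$lambda)
    # t+1 individuals with the preassigned sources
    par1 <- stats::runif(length(idx1)) < rate[idx1]
    parasitoid1 <- rep(NA_character_, length(idx1))
    for (h in unique(idx1[par1])) {
      sel <- which(par1 & idx1 == h)
      w <- affinity[h, ]
      if (sum(w) == 0) { par1[sel] <- FALSE; next }
      parasitoid1[sel] <- sample(colnames(affinity), length(sel),
                                 replace = TRUE, prob = w)
    }
    reared1 <- stats::runif(length(idx1)) < cfg$rearing_success
    occ1 <- list(df = if (length(idx1)) data.frame(
      host_row = idx1, parasitized = par1, parasitoid = parasitoid1,
      source = src1, reared = reared1, stringsAsFactors = FALSE) else NULL)
    validation[[2 * v - 1]] <- occasion_records(
      occ0, hosts, prefix = sprintf("%s-B-", sid), dataset = "validation",
      site_id = sid, block_id = design$block_id[v], round = NA_integer_,
      timestep = "before")
    validation[[2 * v]] <- occasion_records(
      occ1, hosts, prefix = sprintf("%s-A-", sid), dataset = "validation",
      site_id = sid, block_id = design$block_id[v], round = NA_integer_,
      timestep = "after")
    truth_rates[[v]] <- data.frame(site_id = sid, key = hosts$key,
                                   host_taxon = hosts$taxon,
                                   habitat = hosts$habitat, rate = rate,
                                   stringsAsFactors = FALSE)
  }
  validation <- as_rearing_records(
    do.call(rbind, validation[!vapply(validation, is.null, TRUE)]))

  structure(list(
    training = training, validation = validation, design = design,
    truth = list(affinity = affinity, d_true = d_true,
                 rates = do.call(rbind, truth_rates), config = cfg)),
    class = "scenario")
}

check_integral <- function(x, what) {
  bad <- abs(x - round(x)) > 1e-9
  if (any(bad)) {
    stop_edgeweb("deterministic mode requires integral expectations; ",
                 what, " is non-integral at: ",
                 paste(utils::head(names(x)[bad] %||% which(bad), 5),
                       collapse = ", "))
  }
  as.integer(round(x))
}

#' Deterministic expectation-mode scenario
#'
#' Replaces the generator's random draws by their expectations: fixed
#' abundances per host (the configured habitat means, which must be
#' integers), exact transect/extra splits, exact attack counts at `t`
#' (`n * p_base`) split evenly over each host's parasitoid links, and exact
#' rearing thinning. The affinity web is uniform with a fixed per-host
#' degree chosen from the connectance target. Abundance, attack,
#' attribution, sampling and rearing expectations must all be integral or
#' the offending quantity is reported as an error. Attack counts at `t+1`
#' (whose expectations are ratio-valued under `lambda = 1`) are realized by
#' largest-remainder rounding; these affect only observed rates, never the
#' expected-rate round trip.
#'
#' Used for exact round-trip tests: the pipeline's expected parasitism rate
#' computed from the emitted records reproduces the generator's true rates
#' to machine precision.
#'
#' @param config A [scenario_config()]; `rearing_success` and the abundance
#'   means must make all realized counts integral.
#' @return A `scenario` list as from [generate_scenario()].
#' @export
deterministic_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  hosts <- community_hosts(cfg)
  affinity <- draw_affinity(cfg, hosts, deterministic = TRUE)
  deg <- sum(affinity[1, ] > 0)
  p_eff <- rep(cfg$p_base, nrow(hosts))
  mean_h <- unname(cfg$abund_mean[hosts$habitat])

  n0 <- check_integral(stats::setNames(mean_h, hosts$key),
                       "abundance mean")
  n_tr <- check_integral(
    stats::setNames(n0 * (1 - cfg$extra_fraction), hosts$key),
    "transect count n * (1 - extra_fraction)")
  attacks0 <- check_integral(stats::setNames(n0 * cfg$p_base, hosts$key),
                             "attack count n * p_base")
  if (any(attacks0 %% deg != 0)) {
    stop_edgeweb("deterministic mode requires attack counts divisible by ",
                 "the per-host degree ", deg, "; offending host(s): ",
                 paste(utils::head(hosts$key[attacks0 %% deg != 0], 5),
                       collapse = ", "))
  }
  check_integral(stats::setNames(n0 * cfg$rearing_success, hosts$key),
                 "reared count n * rearing_success")
  attacks_obs0 <- check_integral(
    stats::setNames(attacks0 * cfg$rearing_success, hosts$key),
    "reared attack count attacks * rearing_success")
  check_integral(
    stats::setNames(attacks0 / deg * cfg$rearing_success, hosts$key),
    "per-parasitoid reared attacks (attacks / degree * rearing_success)")

  share <- affinity / ifelse(rowSums(affinity) > 0, rowSums(affinity), 1)
  C_true <- share * (n0 * cfg$p_base)
  d_true <- true_dependence(C_true)

  # one deterministic occasion: fixed counts, exact splits
  det_occasion <- function(n_vec, attack_vec) {
    rows <- lapply(seq_len(nrow(hosts)), function(h) {
      n <- n_vec[h]
      if (n == 0) return(NULL)
      atk <- attack_vec[h]
      parasitoid <- rep(NA_character_, n)
      reared_par <- logical(0)
      if (atk > 0) {
        per <- apportion(atk, rep(1, deg))
        parasitoid[seq_len(atk)] <- rep(colnames(affinity)[affinity[h, ] > 0],
                                        per)
        # rearing thins each (host, parasitoid) cell by the same fraction,
        # preserving the web's relative structure exactly
        reared_par <- unlist(lapply(per, function(cnt) {
          rk <- as.integer(round(cnt * cfg$rearing_success))
          c(rep(TRUE, rk), rep(FALSE, cnt - rk))
        }))
      }
      ntr <- check_integral(
        stats::setNames(n * (1 - cfg$extra_fraction), hosts$key[h]),
        "transect split")
      src <- c(rep("transect", ntr), rep("extra", n - ntr))
      ru <- as.integer(round((n - atk) * cfg$rearing_success))
      reared <- c(reared_par,
                  rep(TRUE, ru), rep(FALSE, n - atk - ru))
      data.frame(host_row = h, parasitized = seq_len(n) <= atk,
                 parasitoid = parasitoid, source = src, reared = reared,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    list(df = df,
         attacks = attack_vec,
         n_transect = stats::setNames(
           as.integer(n_vec * (1 - cfg$extra_fraction)), NULL))
  }

  training <- list()
  k <- 0
  for (s in seq_len(cfg$n_training_sites)) {
    for (r in seq_len(cfg$n_rounds)) {
      occ <- det_occasion(n0, attacks0)
      k <- k + 1
      training[[k]] <- occasion_records(
        occ, hosts, prefix = sprintf("T%02d%02d-", s, r),
        dataset = "training", site_id = sprintf("T%02d", s),
        block_id = "regional", round = r, timestep = NA_character_)
    }
  }
  training <- as_rearing_records(do.call(rbind, training))

  design <- data.frame(
    site_id = sprintf("V%02d", seq_len(2 * cfg$n_blocks)),
    block_id = sprintf("B%02d", rep(seq_len(cfg$n_blocks), each = 2)),
    treatment = rep(c("reduction", "control"), cfg$n_blocks),
    stringsAsFactors = FALSE)

  validation <- list()
  truth_rates <- list()
  for (v in seq_len(nrow(design))) {
    sid <- design$site_id[v]
    treated <- design$treatment[v] == "reduction"
    mult <- ifelse(treated & hosts$habitat == "P", cfg$reduction_factor,
                   cfg$decline_factor)
    n1 <- check_integral(stats::setNames(n0 * mult, hosts$key),
                         "t+1 abundance n * factor")
    n_tr1 <- check_integral(
      stats::setNames(n1 * (1 - cfg$extra_fraction), hosts$key),
      "t+1 transect split")
    occ0 <- det_occasion(n0, attacks0)
    # truth on the observed (post-rearing) attack basis, the same basis the
    # pipeline measures; rearing thins webs and attack totals uniformly
    rate <- true_rates_for_site(d_true, attacks_obs0, n_tr, n_tr1, n1,
                                p_eff * cfg$rearing_success, cfg$lambda)
    attacks1 <- as.integer(round(rate * n1))  # largest-remainder per host
    attacks1 <- pmin(attacks1, n1)
    # keep attribution feasible: realized reared splits need not be exact
    # at t+1 (rounding is documented); rearing stays exact per individual
    occ1 <- det_occasion(n1, attacks1)
    validation[[2 * v - 1]] <- occasion_records(
      occ0, hosts, prefix = sprintf("%s-B-", sid), dataset = "validation",
      site_id = sid, block_id = design$block_id[v], round = NA_integer_,
      timestep = "before")
    validation[[2 * v]] <- occasion_records(
      occ1, hosts, prefix = sprintf("%s-A-", sid), dataset = "validation",
      site_id = sid, block_id = design$block_id[v], round = NA_integer_,
      timestep = "after")
    truth_rates[[v]] <- data.frame(site_id = sid, key = hosts$key,
                                   host_taxon = hosts$taxon,
                                   habitat = hosts$habitat, rate = rate,
                                   stringsAsFactors = FALSE)
  }
  validation <- as_rearing_records(do.call(rbind, validation))

  structure(list(
    training = training, validation = validation, design = design,
    truth = list(affinity = affinity, d_true = d_true,
                 rates = do.call(rbind, truth_rates), config = cfg)),
    class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario> %d training + %d validation records; %d sites, %d blocks\n",
    nrow(x$training), nrow(x$validation), nrow(x$design),
    length(unique(x$design$block_id))))
  invisible(x)
}

#' Random quantitative web for property tests
#'
#' Draws a small habitat-indexed web with independent cell counts; some
#' taxa occur in both habitats so cross-habitat structure is present.
#'
#' @param n_hosts,n_parasitoids Web dimensions.
#' @param fill Probability a cell carries at least one attack.
#' @param max_count Maximum per-cell attack count.
#' @param habitats Habitat labels to sample from.
#' @param seed Optional seed.
#' @return A `quantweb`.
#' @export
random_quantweb <- function(n_hosts = 8, n_parasitoids = 5, fill = 0.35,
                            max_count = 6, habitats = c("P", "N"),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_taxa <- max(2, ceiling(n_hosts * 0.7))
  combos <- expand.grid(taxon = sprintf("H%03d", seq_len(n_taxa)),
                        habitat = habitats, stringsAsFactors = FALSE)
  pick <- combos[sample.int(nrow(combos), min(n_hosts, nrow(combos))), ]
  pick <- pick[order(pick$taxon, pick$habitat, method = "radix"), ,
               drop = FALSE]
  H <- nrow(pick)
  counts <- matrix(stats::rbinom(H * n_parasitoids, 1, fill) *
                     sample.int(max_count, H * n_parasitoids,
                                replace = TRUE),
                   H, n_parasitoids)
  quantweb(counts, pick, sprintf("W%03d", seq_len(n_parasitoids)),
           habitat_indexed = length(habitats) > 1)
}

#' Random site panel for property tests
#'
#' Builds a site panel covering every host of a dependence matrix (or an
#' explicit host registry), with positive transect abundances at `t` so no
#' partner terms are dropped. With `equal_abundance = TRUE` the `t+1`
#' abundances equal the `t` abundances on both bases, the regime in which
#' the expected rate collapses to the initial rate.
#'
#' @param hosts A `dependence_matrix`, `quantweb`, or data frame with
#'   `taxon` and `habitat`.
#' @param mean_n Mean abundance scale.
#' @param equal_abundance Force `n(t+1) = n(t)` on both bases.
#' @param site_id,block_id,treatment Panel labels.
#' @param seed Optional seed.
#' @return A `site_panel`.
#' @export
random_site_panel <- function(hosts, mean_n = 8, equal_abundance = FALSE,
                              site_id = "V01", block_id = "B01",
                              treatment = "control", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(hosts, "dependence_matrix")) hosts <- hosts$hosts
  if (inherits(hosts, "quantweb")) hosts <- hosts$hosts
  H <- nrow(hosts)
  n_transect_t <- 1L + stats::rpois(H, mean_n)
  extra_t <- stats::rpois(H, mean_n * 0.2)
  n_total_t <- n_transect_t + extra_t
  if (equal_abundance) {
    n_transect_t1 <- n_transect_t
    n_total_t1 <- n_total_t
  } else {
    n_transect_t1 <- stats::rpois(H, mean_n)
    n_total_t1 <- n_transect_t1 + stats::rpois(H, mean_n * 0.2)
  }
  reared_t <- stats::rbinom(H, n_total_t, 0.8)
  reared_t1 <- stats::rbinom(H, n_total_t1, 0.8)
  attacks_t <- stats::rbinom(H, reared_t, 0.5)
  attacks_t1 <- stats::rbinom(H, reared_t1, 0.4)
  site_panel(data.frame(
    host_taxon = hosts$taxon, habitat = hosts$habitat,
    n_transect_t = n_transect_t, n_transect_t1 = n_transect_t1,
    n_total_t = n_total_t, n_total_t1 = n_total_t1,
    reared_t = reared_t, reared_t1 = reared_t1,
    attacks_t = attacks_t, attacks_t1 = attacks_t1,
    stringsAsFactors = FALSE),
    site_id = site_id, block_id = block_id, treatment = treatment)
}
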