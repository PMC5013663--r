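#' Expected parasitism rate from apparent-competition linkages
#'
#' Predicts the parasitism rate of each focal host at the later timestep
#' from (i) its attack total at the earlier timestep, (ii) the regional
#' dependence matrix `d`, and (iii) the abundance change of every host it
#' shares parasitoids with. For focal host `i` (habitat `A`), the
#' per-partner term is
#' `d[iA, jB] * (attacks_i(t) / n_jB(t)) * n_jB(t+1)`;
#' terms are summed over partners `j` and divided by `n_iA(t+1)`. Partner
#' abundances `n_jB` are on the transect-only basis; the focal attack total
#' and the `n_iA(t+1)` denominator are on the transect-plus-extra basis
#' (matching how attack totals are measured). Rates above 1 are clipped to 1
#' (`E = min(E_raw, 1)`); parasitism rate is host-centric, so rates above 1
#' are not possible.
#'
#' Partners are every host collected at the site, whether or not it was
#' parasitized or reared successfully; partners absent from the regional
#' web contribute `d = 0`; partners with `n_jB(t) = 0` (never seen on the
#' transects before) are dropped with a warning, since their per-capita
#' recruitment is undefined.
#'
#' A focal row is *included* only if the host was collected and successfully
#' reared at both timesteps and was parasitized at the first; other rows are
#' returned with an exclusion reason, never as errors.
#'
#' @param dep A `dependence_matrix` from the regional training web
#'   (full-pool for the headline analysis).
#' @param panel A `site_panel`.
#' @param scope Which partner habitats contribute: `"both"` (default),
#'   `"own"` (the focal's habitat), or `"cross"` (the other habitat).
#' @param exclude_within_intraspecific Drop terms with the same taxon in the
#'   same habitat (`i = j`, `A = B`), removing within-habitat delayed
#'   density dependence; cross-habitat self terms are retained.
#' @param quiet Suppress the dropped-partner warning.
#' @return A data frame, one row per host in the panel, with `E_raw`, `E`
#'   (clipped), `E_within`, `E_cross`, `E_noself`, inclusion flags and
#'   `n_dropped_partners`.
#' @export
expected_parasitism <- function(dep, panel,
                                scope = c("both", "own", "cross"),
                                exclude_within_intraspecific = FALSE,
                                quiet = FALSE) {
  scope <- match.arg(scope)
  stopifnot(inherits(dep, "dependence_matrix"), inherits(panel, "site_panel"))
  d <- panel$data

  # partner quantities (transect-only basis)
  ratio <- rep(0, nrow(d))
  usable <- d$n_transect_t > 0
  ratio[usable] <- d$n_transect_t1[usable] / d$n_transect_t[usable]
  dropped <- !usable
  if (any(dropped) && !quiet) {
    warning(sprintf(
      "site %s: %d partner host(s) with zero transect abundance at t dropped from expected-rate terms",
      panel$site_id, sum(dropped)), call. = FALSE)
  }

  # dependence lookup: focal rows and partner columns, 0 where absent
  D <- matrix(0, nrow(d), nrow(d), dimnames = list(d$key, d$key))
  ri <- match(d$key, dep$hosts$key)
  cj <- match(d$key, dep$sources$key)
  ok_r <- which(!is.na(ri))
  ok_c <- which(!is.na(cj))
  if (length(ok_r) && length(ok_c)) {
    D[ok_r, ok_c] <- dep$values[ri[ok_r], cj[ok_c], drop = FALSE]
  }

  per_capita <- ifelse(d$n_total_t1 > 0, d$attacks_t / d$n_total_t1, NA_real_)
  contrib <- D * rep(ratio, each = nrow(d))          # contrib[i, j]
  same_hab <- outer(d$habitat, d$habitat, "==")
  same_tax <- outer(d$host_taxon, d$host_taxon, "==")

  sum_scope <- function(mask) per_capita * rowSums(contrib * mask)
  E_all <- sum_scope(matrix(TRUE, nrow(d), nrow(d)))
  E_within <- sum_scope(same_hab)
  E_cross <- sum_scope(!same_hab)
  E_noself_raw <- E_all - sum_scope(same_hab & same_tax)

  E_raw <- switch(scope, both = E_all, own = E_within, cross = E_cross)
  if (exclude_within_intraspecific) {
    E_raw <- E_raw - sum_scope(same_hab & same_tax &
                                 switch(scope,
                                        both = matrix(TRUE, nrow(d), nrow(d)),
                                        own = same_hab,
                                        cross = !same_hab))
  }

  reason <- rep(NA_character_, nrow(d))
  reason[d$attacks_t == 0] <- "unparasitized at t"
  reason[d$reared_t1 == 0] <- "not reared at t+1"
  reason[d$reared_t == 0] <- "not reared at t"
  reason[d$n_total_t1 == 0] <- "absent at t+1"
  reason[d$n_total_t == 0] <- "absent at t"
  included <- is.na(reason)

  data.frame(
    key = d$key, host_taxon = d$host_taxon, habitat = d$habitat,
    E_raw = E_raw, E = pmin(E_raw, 1),
    E_within = E_within, E_cross = E_cross,
    E_noself = pmin(E_noself_raw, 1),
    included = included, exclusion_reason = reason,
    n_dropped_partners = sum(dropped),
    stringsAsFactors = FALSE)
}

#' Within- and cross-habitat components of the expected rate
#'
#' Splits each focal host's expected parasitism rate into the contribution
#' of partners in its own habitat and partners across the habitat edge.
#' Both components use the same full-pool dependence matrix, so the pre-clip
#' identity `E_within + E_cross = E_raw` holds exactly.
#'
#' @inheritParams expected_parasitism
#' @return A data frame with `E_within` and `E_cross` per host.
#' @export
decompose_expected <- function(dep, panel, quiet = FALSE) {
  out <- expected_parasitism(dep, panel, scope = "both", quiet = quiet)
  out[c("key", "host_taxon", "habitat", "E_within", "E_cross", "E_raw",
        "included", "exclusion_reason")]
}

#' Observed parasitism rate at the later timestep
#'
#' Parasitism events divided by hosts sampled, both on the transect-plus-
#' extra basis at `t+1`. Hosts absent at `t+1` get `NA` (excluded rows, not
#' errors).
#'
#' @param panel A `site_panel`.
#' @return Named numeric vector over the panel's hosts.
#' @export
observed_parasitism <- function(panel) {
  stopifnot(inherits(panel, "site_panel"))
  d <- panel$data
  stats::setNames(ifelse(d$n_total_t1 > 0, d$attacks_t1 / d$n_total_t1,
                         NA_real_), d$key)
}

#' Initial parasitism rate at the earlier timestep
#'
#' As [observed_parasitism()] but at `t`: attacks over hosts sampled, both
#' transect-plus-extra.
#'
#' @param panel A `site_panel`.
#' @return Named numeric vector over the panel's hosts.
#' @export
initial_parasitism <- function(panel) {
  stopifnot(inherits(panel, "site_panel"))
  d <- panel$data
  stats::setNames(ifelse(d$n_total_t > 0, d$attacks_t / d$n_total_t,
                         NA_real_), d$key)
}

#' Change in host abundance between timesteps
#'
#' `n(t+1) - n(t)` on the transect-only basis (the standardized abundance
#' measure). Hosts absent at both timesteps return 0.
#'
#' @param panel A `site_panel`.
#' @return Named numeric vector over the panel's hosts.
#' @export
abundance_change <- function(panel) {
  stopifnot(inherits(panel, "site_panel"))
  d <- panel$data
  stats::setNames(as.numeric(d$n_transect_t1 - d$n_transect_t), d$key)
}

#' Assemble the per-host prediction table across sites
#'
#' One row per (site, habitat-indexed host) with the expected (`E`, plus
#' raw, within, cross, and intraspecific-excluded variants), observed (`O`)
#' and initial (`I`) parasitism rates, abundance change (`dN`), binomial
#' event/trial counts, and inclusion flags. Exclusions are data, not
#' exceptions.
#'
#' @param dep A full-pool `dependence_matrix` from the training metaweb.
#' @param panels A list of `site_panel` objects (see [site_panels()]).
#' @param exclude_within_intraspecific Passed through to the expected-rate
#'   computation for the headline `E` columns (the `E_noself` column is
#'   always provided).
#' @param quiet Suppress dropped-partner warnings.
#' @return A `prediction_table` data frame.
#' @export
assemble_prediction_table <- function(dep, panels,
                                      exclude_within_intraspecific = FALSE,
                                      quiet = FALSE) {
  if (inherits(panels, "site_panel")) panels <- list(panels)
  rows <- lapply(panels, function(p) {
    e <- expected_parasitism(
      dep, p, scope = "both",
      exclude_within_intraspecific = exclude_within_intraspecific,
      quiet = quiet)
    d <- p$data
    data.frame(
      site_id = p$site_id, block_id = p$block_id, treatment = p$treatment,
      host_taxon = e$host_taxon, habitat = e$habitat,
      E = e$E, E_raw = e$E_raw, E_within = e$E_within, E_cross = e$E_cross,
      E_noself = e$E_noself,
      O = unname(observed_parasitism(p)),
      I = unname(initial_parasitism(p)),
      dN = unname(abundance_change(p)),
      events = d$attacks_t1, trials = d$n_total_t1,
      n_after = d$n_total_t1,
      included = e$included, exclusion_reason = e$exclusion_reason,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Write a prediction table to CSV
#'
#' @param table A `prediction_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(table, path) {
  out <- as.data.frame(table)
  out$exclusion_reason[is.na(out$exclusion_reason)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
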