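#' Construct a site panel
#'
#' A site panel holds, for one validation site, the per-host quantities
#' needed by the prediction stage at the two BACI timesteps: attack totals
#' (transect plus extra basis), reared counts, and abundances on both the
#' transect-only and transect-plus-extra bases.
#'
#' @param data Data frame with one row per habitat-indexed host and columns
#'   `host_taxon, habitat, n_transect_t, n_transect_t1, n_total_t,
#'   n_total_t1, reared_t, reared_t1, attacks_t, attacks_t1`.
#' @param site_id,block_id Site and spatial-block labels.
#' @param treatment `"reduction"` or `"control"`.
#' @return A `site_panel` object.
#' @export
site_panel <- function(data, site_id, block_id,
                       treatment = c("control", "reduction")) {
  treatment <- match.arg(treatment)
  need <- c("host_taxon", "habitat", "n_transect_t", "n_transect_t1",
            "n_total_t", "n_total_t1", "reared_t", "reared_t1",
            "attacks_t", "attacks_t1")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop_edgeweb("site panel is missing column(s): ",
                 paste(missing, collapse = ", "))
  }
  data <- as.data.frame(data)[need]
  num <- need[-(1:2)]
  for (col in num) data[[col]] <- as.integer(data[[col]])
  if (any(vapply(data[num], function(x) any(is.na(x) | x < 0), TRUE))) {
    stop_edgeweb("site-panel counts must be non-negative integers")
  }
  bad <- with(data, attacks_t > reared_t | attacks_t1 > reared_t1 |
                reared_t > n_total_t | reared_t1 > n_total_t1 |
                n_transect_t > n_total_t | n_transect_t1 > n_total_t1)
  if (any(bad)) {
    stop_edgeweb("site-panel invariant violated (attacks <= reared <= ",
                 "n_total; n_transect <= n_total) for host(s): ",
                 paste(utils::head(data$host_taxon[bad], 5), collapse = ", "))
  }
  data$key <- host_key(data$host_taxon, data$habitat)
  if (anyDuplicated(data$key)) stop_edgeweb("duplicate hosts in site panel")
  data <- data[order(data$host_taxon, data$habitat, method = "radix"), ,
               drop = FALSE]
  rownames(data) <- NULL
  structure(list(data = data, site_id = site_id, block_id = block_id,
                 treatment = treatment),
            class = "site_panel")
}

#' @export
print.site_panel <- function(x, ...) {
  cat(sprintf("<site_panel> %s (block %s, %s): %d hosts\n",
              x$site_id, x$block_id, x$treatment, nrow(x$data)))
  invisible(x)
}

#' Assemble site panels from validation records
#'
#' Tabulates, per validation site and habitat-indexed host, the abundances
#' (both bases), reared counts and attack totals at the `before` and
#' `after` timesteps.
#'
#' @param records A `rearing_records` data frame.
#' @param design Data frame mapping `site_id` to `block_id` and `treatment`
#'   (`"control"`/`"reduction"`). If `NULL`, `block_id` is taken from the
#'   records and every site is labelled `"control"`.
#' @return A named list of `site_panel` objects.
#' @export
site_panels <- function(records, design = NULL) {
  records <- as_rearing_records(records)
  recs <- records[records$dataset == "validation", , drop = FALSE]
  if (nrow(recs) == 0) stop_edgeweb("no validation records present")
  if (is.null(design)) {
    design <- unique(recs[c("site_id", "block_id")])
    design$treatment <- "control"
  }
  stopifnot(all(c("site_id", "block_id", "treatment") %in% names(design)))
  count_by <- function(d, sid) {
    hosts <- unique(d[c("host_taxon", "habitat")])
    k <- function(tax, hab, ts) paste(tax, hab, ts, sep = "\r")
    cnt <- function(sub, ts) {
      tab <- table(k(sub$host_taxon, sub$habitat,
                     sub$timestep)[sub$timestep == ts])
      keys <- k(hosts$host_taxon, hosts$habitat, ts)
      as.integer(ifelse(keys %in% names(tab), tab[keys], 0L))
    }
    data.frame(
      host_taxon = hosts$host_taxon, habitat = hosts$habitat,
      n_transect_t = cnt(d[d$source == "transect", ], "before"),
      n_transect_t1 = cnt(d[d$source == "transect", ], "after"),
      n_total_t = cnt(d, "before"),
      n_total_t1 = cnt(d, "after"),
      reared_t = cnt(d[d$reared_ok, ], "before"),
      reared_t1 = cnt(d[d$reared_ok, ], "after"),
      attacks_t = cnt(d[!is.na(d$parasitoid_taxon), ], "before"),
      attacks_t1 = cnt(d[!is.na(d$parasitoid_taxon), ], "after"),
      stringsAsFactors = FALSE)
  }
  sites <- sort(unique(recs$site_id))
  panels <- lapply(sites, function(sid) {
    d <- recs[recs$site_id == sid, , drop = FALSE]
    row <- design[design$site_id == sid, , drop = FALSE]
    if (nrow(row) != 1) {
      stop_edgeweb("design table must have exactly one row for site ", sid)
    }
    site_panel(count_by(d, sid), site_id = sid, block_id = row$block_id,
               treatment = row$treatment)
  })
  stats::setNames(panels, sites)
}
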