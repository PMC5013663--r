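#' Construct a quantitative host-parasitoid web
#'
#' A `quantweb` is a host x parasitoid matrix of attack (rearing-event)
#' counts, with an explicit host registry. When the web is habitat-indexed,
#' the same taxon in plantation (`P`) and native (`N`) forest occupies two
#' distinct rows everywhere downstream, which is what permits cross-habitat
#' dependence terms.
#'
#' @param counts Non-negative integer matrix, hosts in rows, parasitoids in
#'   columns.
#' @param hosts Data frame with columns `taxon` and `habitat` (`habitat` may
#'   be `NA` for a non-indexed web), one row per matrix row.
#' @param parasitoids Character vector of parasitoid labels, one per column.
#' @param habitat_indexed Logical; whether hosts are habitat-indexed.
#' @param basis `"quantitative"` or `"binary"`.
#' @param provenance Free-form list recording the filter that produced the
#'   web (sites, rounds, sources, ...).
#' @return A `quantweb` object.
#' @export
quantweb <- function(counts, hosts, parasitoids,
                     habitat_indexed = TRUE,
                     basis = c("quantitative", "binary"),
                     provenance = list()) {
  basis <- match.arg(basis)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0)) {
    stop_edgeweb("web counts must be non-negative integers")
  }
  hosts <- as.data.frame(hosts, stringsAsFactors = FALSE)
  if (!all(c("taxon", "habitat") %in% names(hosts))) {
    stop_edgeweb("hosts must have columns 'taxon' and 'habitat'")
  }
  if (nrow(hosts) != nrow(counts)) {
    stop_edgeweb("hosts registry length does not match count matrix rows")
  }
  if (length(parasitoids) != ncol(counts)) {
    stop_edgeweb("parasitoid registry length does not match matrix columns")
  }
  hosts$key <- host_key(hosts$taxon, if (habitat_indexed) hosts$habitat
                        else NA_character_)
  if (anyDuplicated(hosts$key)) {
    stop_edgeweb("duplicate host entries in registry")
  }
  rownames(counts) <- hosts$key
  colnames(counts) <- as.character(parasitoids)
  structure(list(counts = counts, hosts = hosts,
                 parasitoids = as.character(parasitoids),
                 habitat_indexed = isTRUE(habitat_indexed),
                 basis = basis, provenance = provenance),
            class = "quantweb")
}

#' @export
print.quantweb <- function(x, ...) {
  cat(sprintf("<quantweb> %d host%s x %d parasitoid%s (%s%s)\n",
              nrow(x$counts), if (nrow(x$counts) == 1) "" else "s",
              ncol(x$counts), if (ncol(x$counts) == 1) "" else "s",
              x$basis,
              if (x$habitat_indexed) ", habitat-indexed" else ""))
  cat(sprintf("  total attacks: %d; parasitized hosts: %d\n",
              sum(x$counts), sum(rowSums(x$counts) > 0)))
  invisible(x)
}

#' Hosts with at least one recorded attack
#'
#' @param web A `quantweb`.
#' @return Logical vector over the host registry.
#' @export
parasitized_hosts <- function(web) {
  stopifnot(inherits(web, "quantweb"))
  if (ncol(web$counts) == 0) {
    return(stats::setNames(rep(FALSE, nrow(web$counts)), web$hosts$key))
  }
  stats::setNames(rowSums(web$counts) > 0, web$hosts$key)
}

filter_records <- function(records, dataset = NULL, sites = NULL,
                           rounds = NULL, sources = NULL, timesteps = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(dataset)) keep <- keep & records$dataset %in% dataset
  if (!is.null(sites)) keep <- keep & records$site_id %in% sites
  if (!is.null(rounds)) keep <- keep & records$round %in% rounds
  if (!is.null(sources)) keep <- keep & records$source %in% sources
  if (!is.null(timesteps)) keep <- keep & records$timestep %in% timesteps
  records[keep, , drop = FALSE]
}

#' Build a quantitative web from rearing records
#'
#' Counts parasitism events per (host, parasitoid) pair over the records
#' that pass the provenance filter. Every collected host enters the registry
#' (hosts never successfully reared included), but only reared parasitism
#' events produce counts; hosts with an all-zero row are retained and can be
#' identified with [parasitized_hosts()]. Registries are sorted by (taxon,
#' habitat) so the matrix is reproducible regardless of record order.
#'
#' @param records A `rearing_records` data frame.
#' @param dataset,sites,rounds,sources,timesteps Optional provenance
#'   filters; `NULL` keeps everything.
#' @param habitat_indexed If `TRUE` (default) the same taxon in the two
#'   habitats forms two distinct hosts.
#' @return A `quantweb`.
#' @export
build_web <- function(records, dataset = NULL, sites = NULL, rounds = NULL,
                      sources = NULL, timesteps = NULL,
                      habitat_indexed = TRUE) {
  records <- as_rearing_records(records)
  recs <- filter_records(records, dataset, sites, rounds, sources, timesteps)
  if (nrow(recs) == 0) {
    stop_edgeweb("no rearing records left after applying the filter",
                 class = "edgeweb_empty_web_error")
  }
  habitat <- if (habitat_indexed) recs$habitat else NA_character_
  key <- host_key(recs$host_taxon, habitat)
  reg <- unique(data.frame(taxon = recs$host_taxon,
                           habitat = if (habitat_indexed) recs$habitat
                                     else NA_character_,
                           key = key, stringsAsFactors = FALSE))
  reg <- reg[order(reg$taxon, reg$habitat, method = "radix"), , drop = FALSE]
  rownames(reg) <- NULL

  events <- recs[!is.na(recs$parasitoid_taxon), , drop = FALSE]
  parasitoids <- sort(unique(events$parasitoid_taxon))
  counts <- matrix(0L, nrow(reg), length(parasitoids),
                   dimnames = list(reg$key, parasitoids))
  if (nrow(events)) {
    ev_key <- host_key(events$host_taxon,
                       if (habitat_indexed) events$habitat else NA_character_)
    tab <- table(factor(ev_key, levels = reg$key),
                 factor(events$parasitoid_taxon, levels = parasitoids))
    counts <- matrix(as.integer(tab), nrow(reg), length(parasitoids),
                     dimnames = list(reg$key, parasitoids))
  }
  quantweb(counts, reg[c("taxon", "habitat")], parasitoids,
           habitat_indexed = habitat_indexed,
           provenance = list(dataset = dataset, sites = sites,
                             rounds = rounds, sources = sources,
                             timesteps = timesteps,
                             n_records = nrow(recs),
                             n_events = nrow(events)))
}

#' Pool webs into a metaweb
#'
#' Unions host and parasitoid registries and sums counts cell-wise. This is
#' how the regional metaweb is produced: interaction data pooled across
#' sites and sampling dates but kept separate by forest type.
#'
#' @param webs A list of `quantweb` objects (all habitat-indexed or all
#'   non-indexed, same basis).
#' @return A pooled `quantweb`.
#' @export
pool_metaweb <- function(webs) {
  if (inherits(webs, "quantweb")) webs <- list(webs)
  stopifnot(length(webs) >= 1, all(vapply(webs, inherits, TRUE, "quantweb")))
  idx <- vapply(webs, function(w) w$habitat_indexed, TRUE)
  if (length(unique(idx)) > 1) {
    stop_edgeweb("cannot pool habitat-indexed and non-indexed webs")
  }
  basis <- unique(vapply(webs, function(w) w$basis, ""))
  if (length(basis) > 1) {
    stop_edgeweb("cannot pool webs with different bases")
  }
  hosts <- unique(do.call(rbind, lapply(webs, function(w)
    w$hosts[c("taxon", "habitat")])))
  hosts <- hosts[order(hosts$taxon, hosts$habitat, method = "radix"), ,
                 drop = FALSE]
  rownames(hosts) <- NULL
  keys <- host_key(hosts$taxon, if (idx[1]) hosts$habitat else NA_character_)
  parasitoids <- sort(unique(unlist(lapply(webs, function(w) w$parasitoids))))
  counts <- matrix(0L, length(keys), length(parasitoids),
                   dimnames = list(keys, parasitoids))
  for (w in webs) {
    if (nrow(w$counts) && ncol(w$counts)) {
      counts[rownames(w$counts), colnames(w$counts)] <-
        counts[rownames(w$counts), colnames(w$counts)] + w$counts
    }
  }
  quantweb(counts, hosts, parasitoids, habitat_indexed = idx[1],
           basis = basis,
           provenance = list(pooled = lapply(webs, function(w) w$provenance)))
}

#' Binary connectance of a web
#'
#' The fraction of realized links, `L / (H_q * P)`, where `L` is the number
#' of host-parasitoid cells with at least one attack, `H_q` the number of
#' (habitat-indexed) hosts and `P` the number of parasitoid species.
#'
#' @param web A `quantweb`.
#' @return A number in `[0, 1]`.
#' @export
binary_connectance <- function(web) {
  stopifnot(inherits(web, "quantweb"))
  if (nrow(web$counts) == 0 || ncol(web$counts) == 0) {
    stop_edgeweb("connectance is undefined for an empty web")
  }
  sum(web$counts > 0) / (nrow(web$counts) * ncol(web$counts))
}

#' Reduce a web to link presence/absence
#'
#' Every positive attack count becomes 1. Used for the binary-web variant of
#' the expected-rate predictions.
#'
#' @param web A `quantweb`.
#' @return A `quantweb` with `basis = "binary"`.
#' @export
binarize_web <- function(web) {
  stopifnot(inherits(web, "quantweb"))
  counts <- (web$counts > 0) * 1L
  dimnames(counts) <- dimnames(web$counts)
  quantweb(counts, web$hosts[c("taxon", "habitat")], web$parasitoids,
           habitat_indexed = web$habitat_indexed, basis = "binary",
           provenance = c(web$provenance, list(binarized = TRUE)))
}

#' Abundance table from validation records
#'
#' Counts collected individuals per (site, timestep, host, habitat) on two
#' bases: `n_transect` counts only standardized transect individuals (the
#' abundance measure), `n_total` adds extra-sampling individuals (the basis
#' for per-capita parasitism). Counting includes unparasitized and
#' failed-rearing individuals: abundance is collected individuals, not
#' reared ones. Hosts seen at a site get a zero-filled row for every
#' timestep at that site.
#'
#' @param records A `rearing_records` data frame (validation rows are used).
#' @return A data frame with columns `site_id, timestep, host_taxon,
#'   habitat, n_transect, n_total`.
#' @export
abundance_table <- function(records) {
  records <- as_rearing_records(records)
  recs <- records[records$dataset == "validation", , drop = FALSE]
  if (nrow(recs) == 0) {
    stop_edgeweb("no validation records with timesteps present")
  }
  hosts <- unique(recs[c("site_id", "host_taxon", "habitat")])
  grid <- merge(hosts, data.frame(timestep = c("before", "after")))
  key <- function(d) paste(d$site_id, d$timestep, d$host_taxon, d$habitat,
                           sep = "\r")
  tot <- table(key(recs))
  tra <- table(key(recs[recs$source == "transect", , drop = FALSE]))
  k <- key(grid)
  grid$n_transect <- as.integer(ifelse(k %in% names(tra), tra[k], 0L))
  grid$n_total <- as.integer(ifelse(k %in% names(tot), tot[k], 0L))
  grid <- grid[order(grid$site_id, grid$timestep, grid$host_taxon,
                     grid$habitat, method = "radix"),
               c("site_id", "timestep", "host_taxon", "habitat",
                 "n_transect", "n_total")]
  rownames(grid) <- NULL
  grid
}

#' Export a web as long-format CSV plus a JSON provenance sidecar
#'
#' @param web A `quantweb`.
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_web <- function(web, path) {
  stopifnot(inherits(web, "quantweb"))
  idx <- which(web$counts > 0, arr.ind = TRUE)
  long <- data.frame(
    host_taxon = web$hosts$taxon[idx[, 1]],
    habitat = web$hosts$habitat[idx[, 1]],
    parasitoid_taxon = colnames(web$counts)[idx[, 2]],
    count = web$counts[idx], stringsAsFactors = FALSE)
  long <- long[order(long$host_taxon, long$habitat, long$parasitoid_taxon,
                     method = "radix"), , drop = FALSE]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(basis = web$basis, habitat_indexed = web$habitat_indexed,
         n_hosts = nrow(web$counts), n_parasitoids = ncol(web$counts),
         total_attacks = sum(web$counts), provenance = web$provenance),
    sidecar, auto_unbox = TRUE, null = "null")
  invisible(path)
}
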