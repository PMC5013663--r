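# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
host_key <- function(taxon, habitat) {
  taxon <- as.character(taxon)
  habitat <- rep_len(as.character(habitat), length(taxon))
  ifelse(is.na(habitat) | habitat == "", taxon,
         paste(taxon, habitat, sep = "|"))
}

# Derive a reproducible child seed for a named generator stage; keeps values
# well inside 32-bit integer range.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  k <- sum(utf8ToInt(stage))
  as.integer((abs(as.numeric(seed)) %% 1000003) * 1009 + 97 * k) %% 2147483629L
}

stop_edgeweb <- function(..., class = "edgeweb_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Largest-remainder apportionment of `total` into integer parts proportional
# to `weights`; exact when total * weights / sum(weights) is already integral.
apportion <- function(total, weights) {
  if (total == 0 || sum(weights) == 0) return(rep(0L, length(weights)))
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}
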