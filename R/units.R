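#' Convert between radioactivity units
#'
#' Exact conversions among becquerel- and curie-family units, with optional
#' per-millilitre concentration variants (e.g. `"kBq/mL"`, `"uCi/mL"`). The
#' curie bridge is exact by definition: 1 uCi = 37 kBq.
#'
#' @param value numeric vector of activities (or concentrations).
#' @param from,to unit strings among `Bq`, `kBq`, `MBq`, `uCi`, `mCi`, `Ci`
#'   (aliases `μCi` accepted), each optionally suffixed `/mL` or `/cc`.
#'   Both sides must agree on being plain activities or concentrations.
#' @return numeric vector in the target unit.
#' @examples
#' convert_activity(148, "MBq", "mCi")    # 4.0
#' convert_activity(37, "kBq", "uCi")     # 1
#' convert_activity(151.33, "kBq/mL", "uCi/mL")
#' @export
convert_activity <- function(value, from, to) {
  pf <- parse_activity_unit(from)
  pt <- parse_activity_unit(to)
  if (pf$per_mL != pt$per_mL)
    stop(sprintf("cannot convert between activity and concentration units ('%s' -> '%s')",
                 from, to))
  value * pf$bq / pt$bq
}

# Bq per one unit; exact: 1 Ci = 3.7e10 Bq
parse_activity_unit <- function(u) {
  if (!is.character(u) || length(u) != 1L) stop("unit must be a single string")
  raw <- u
  u <- gsub("μ", "u", u)
  per_mL <- grepl("/(mL|ml|cc)$", u)
  u <- sub("/(mL|ml|cc)$", "", u)
  bq <- switch(u,
    "Bq" = 1, "kBq" = 1e3, "MBq" = 1e6, "GBq" = 1e9,
    "uCi" = 3.7e4, "mCi" = 3.7e7, "Ci" = 3.7e10,
    stop(sprintf("unknown activity unit '%s'", raw)))
  list(bq = bq, per_mL = per_mL)
}
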