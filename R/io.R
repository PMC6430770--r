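#' Read a pool-size table (`pools.csv` schema)
#'
#' Columns: `metabolite`, `fraction` (mito_fraction / cyto_fraction /
#' whole_cell), `value`, `sd`, `n_replicates`, `units`.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_pools_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "fraction", "value", "sd", "n_replicates", "units")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pools table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !df$fraction %in% c("mito_fraction", "cyto_fraction", "whole_cell")
  if (any(bad)) stop("pools table row ", which(bad)[1],
                     ": unknown fraction '", df$fraction[which(bad)[1]], "'")
  if (any(df$value < 0)) stop("pools table row ", which(df$value < 0)[1],
                              ": negative value")
  if (any(df$sd < 0)) stop("pools table row ", which(df$sd < 0)[1],
                           ": negative sd")
  df
}

#' @rdname read_pools_csv
#' @param df Data.frame in the pools schema.
#' @export
write_pools_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a mass-isotopomer table (`mids.csv` schema)
#'
#' Columns: `metabolite`, `compartment_or_fraction`, `time_min`, `m0..mN`,
#' `sd_m0..sd_mN` (columns beyond a metabolite's carbon count are NA). MID
#' rows are renormalized to sum to one; deviations beyond `tol` trigger a
#' warning naming the row.
#'
#' @param path CSV file path.
#' @param tol Tolerated deviation of a row sum from 1 before warning
#'   (default 0.05).
#' @return Validated data.frame with renormalized MID columns.
#' @export
read_mids_csv <- function(path, tol = 0.05) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "compartment_or_fraction", "time_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("MID table missing column(s): ",
                         paste(miss, collapse = ", "))
  m_cols <- grep("^m[0-9]+$", names(df), value = TRUE)
  sd_cols <- grep("^sd_m[0-9]+$", names(df), value = TRUE)
  if (!length(m_cols)) stop("MID table has no m0..mN columns")
  if (length(sd_cols) != length(m_cols)) {
    stop("MID table missing sd column(s): expected one sd_m* per m* column")
  }
  m_cols <- m_cols[order(as.integer(sub("^m", "", m_cols)))]
  sd_cols <- sd_cols[order(as.integer(sub("^sd_m", "", sd_cols)))]
  for (i in seq_len(nrow(df))) {
    x <- as.numeric(df[i, m_cols])
    ok <- !is.na(x)
    if (!any(ok)) stop("MID table row ", i, ": all isotopomer values NA")
    if (any(x[ok] < -1e-9)) stop("MID table row ", i, ": negative fraction")
    s <- sum(x[ok])
    if (s <= 0) stop("MID table row ", i, ": nonpositive row sum")
    if (abs(s - 1) > tol) {
      warning(sprintf("MID row %d (%s, %s, t=%s) sums to %.4f; renormalizing",
                      i, df$metabolite[i], df$compartment_or_fraction[i],
                      df$time_min[i], s))
    }
    df[i, m_cols][ok] <- x[ok] / s
  }
  attr(df, "m_cols") <- m_cols
  attr(df, "sd_cols") <- sd_cols
  df
}

#' @rdname read_mids_csv
#' @param df Data.frame in the mids schema.
#' @export
write_mids_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Extract the (fractions, sds) of one metabolite/fraction/time row.
mid_row <- function(df, metabolite, frac, time) {
  m_cols <- attr(df, "m_cols") %||% grep("^m[0-9]+$", names(df), value = TRUE)
  sd_cols <- attr(df, "sd_cols") %||% grep("^sd_m[0-9]+$", names(df), value = TRUE)
  i <- which(df$metabolite == metabolite &
               df$compartment_or_fraction == frac &
               abs(df$time_min - time) < 1e-9)
  if (length(i) != 1L) {
    stop("expected one MID row for ", metabolite, "/", frac, "/t=", time,
         "; found ", length(i))
  }
  x <- as.numeric(df[i, m_cols]); s <- as.numeric(df[i, sd_cols])
  ok <- !is.na(x)
  list(fractions = x[ok], sds = ifelse(is.na(s[ok]), 0, s[ok]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
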