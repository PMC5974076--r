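#' Indel-percentage differential (nuclease minus mock)
#'
#' The per-site off-target activity measure: percentage of indels in the
#' ZFN-treated sample minus the matched mock (or shared background) sample,
#' rounded half away from zero to 2 decimals. A missing measurement on
#' either side (`NA`, printed as "ND") propagates.
#'
#' @param mock,zfn Indel percentages in `[0, 100]`; `NA` for not determined.
#'   Vectorised.
#' @return Differential percentage(s), `NA`-propagating.
#' @examples
#' compute_differential(0.05, 18.02)  # 17.97
#' @export
compute_differential <- function(mock, zfn) {
  bad <- function(x) !is.na(x) & (x < 0 | x > 100)
  if (any(bad(mock)) || any(bad(zfn)))
    stop("indel percentages must lie in [0, 100]")
  round_half_away(zfn - mock)
}

#' Build a per-site off-target record table
#'
#' One record per site with mock and nuclease indel percentages and their
#' differential. Sites present in only one arm get ND (`NA`) in the missing
#' column and an ND differential.
#'
#' @param mock,zfn Site-keyed inputs for each arm: a named numeric vector of
#'   indel percentages, or a named list of `sample_summary` objects (their
#'   `pct_indels` is used).
#' @param sample Sample label stored on every record.
#' @return Data frame of class `offtarget_records`: site_id, sample,
#'   pct_indels_mock, pct_indels_zfn, differential.
#' @export
build_offtarget_table <- function(mock, zfn, sample = "") {
  mock <- as_site_percentages(mock, "mock")
  zfn <- as_site_percentages(zfn, "zfn")
  sites <- union(names(mock), names(zfn))
  out <- data.frame(
    site_id = sites, sample = sample,
    pct_indels_mock = unname(mock[sites]),
    pct_indels_zfn = unname(zfn[sites]),
    stringsAsFactors = FALSE)
  out$differential <- compute_differential(out$pct_indels_mock,
                                           out$pct_indels_zfn)
  class(out) <- c("offtarget_records", "data.frame")
  out
}

as_site_percentages <- function(x, arm) {
  if (is.list(x) && all(vapply(x, inherits, TRUE, "sample_summary")))
    x <- vapply(x, function(s) s$pct_indels, 0)
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop(sprintf("'%s' must be a site-named numeric vector or list of sample summaries", arm))
  if (anyDuplicated(names(x))) stop(sprintf("duplicate site ids in '%s'", arm))
  x
}

#' Aggregate off-target differentials
#'
#' Mean (2 decimals), minimum and maximum over the non-ND differentials,
#' excluding on-target rows by default (sites whose id starts with "On").
#'
#' @param records An `offtarget_records` data frame (or any data frame with
#'   `site_id` and `differential` columns).
#' @param include_on_target Include on-target rows (default FALSE).
#' @return A `differential_aggregate` list: n_sites_used, mean, min, max,
#'   n_excluded_nd.
#' @export
aggregate_differentials <- function(records, include_on_target = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("site_id", "differential") %in% names(records)))
  rows <- records
  if (!include_on_target)
    rows <- rows[!grepl("^on[-_]?target", rows$site_id, ignore.case = TRUE), ,
                 drop = FALSE]
  d <- rows$differential
  used <- d[!is.na(d)]
  if (length(used) == 0L) stop("no non-ND differentials to aggregate")
  structure(list(n_sites_used = length(used),
                 mean = round_half_away(mean(used)),
                 min = min(used), max = max(used),
                 n_excluded_nd = sum(is.na(d))),
            class = "differential_aggregate")
}

#' @export
print.differential_aggregate <- function(x, ...) {
  cat(sprintf(
    "differential_aggregate: n = %d (ND excluded: %d), mean %.2f%%, range %.2f to %.2f%%\n",
    x$n_sites_used, x$n_excluded_nd, x$mean, x$min, x$max))
  invisible(x)
}

#' Published on/off-target indel table for the Prkdc ZFN
#'
#' The printed per-site indel percentages for ZFN-treated scid fibroblasts
#' and HSPCs (with matched mocks) and for transplanted-mouse tissues
#' (thymus and spleen CD8 T-cells against a shared IDLV spleen background),
#' at the on-target site and 9-10 predicted off-target sites, together with
#' the differentials as printed. These serve as inputs for reproducing the
#' table arithmetic; ND marks measurements not determined.
#'
#' @return Data frame: table, site_id, sample, pct_indels_mock,
#'   pct_indels_zfn, differential_printed (ND as `NA`).
#' @export
prkdc_offtarget_tables <- function() {
  path <- system.file("extdata", "prkdc_offtarget_tables.tsv",
                      package = "editcall", mustWork = TRUE)
  read_offtarget_table(path)
}

#' Read/write an off-target table TSV (ND literal for missing values)
#' @param path TSV path.
#' @return Data frame with `NA` for ND cells.
#' @export
read_offtarget_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "ND")
  for (k in intersect(c("pct_indels_mock", "pct_indels_zfn", "differential",
                        "differential_printed"), names(df)))
    df[[k]] <- as.numeric(df[[k]])
  df
}

#' @rdname read_offtarget_table
#' @param records Data frame to write.
#' @export
write_offtarget_table <- function(records, path) {
  out <- records
  for (k in intersect(c("pct_indels_mock", "pct_indels_zfn", "differential"),
                      names(out))) {
    v <- formatC(out[[k]], format = "f", digits = 2)
    v[is.na(out[[k]])] <- "ND"
    out[[k]] <- v
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
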