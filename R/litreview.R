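#' Canonical connection classes of the literature table
#'
#' Four classes: STN afferents and efferents, and parasubthalamic
#' (paraSTN) afferents and efferents. The paraSTN classes are tracked
#' separately because the parasubthalamic nucleus is described in
#' rodents but not primates.
#'
#' @return Character vector of the four class names.
#' @export
connection_classes <- function() {
  c("STN-afferent", "STN-efferent", "paraSTN-afferent", "paraSTN-efferent")
}

#' Read a connection-count table
#'
#' Expects a CSV with columns `region`, `class`, `count`: the number of
#' tract-tracing reports documenting each regional connection, by
#' connection class. Missing (region, class) combinations are filled
#' with zero counts.
#'
#' @param path CSV path.
#' @return A `data.frame` with one row per (region, class).
#' @export
read_connection_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "class", "count")
  if (!all(need %in% names(df)))
    stop("counts table needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$class), connection_classes())
  if (length(bad) > 0L)
    stop("unknown connection class(es): ", paste(bad, collapse = ", "))
  if (any(df$count < 0) || any(df$count != round(df$count)))
    stop("counts must be non-negative integers")
  full <- expand.grid(region = unique(df$region),
                      class = connection_classes(),
                      stringsAsFactors = FALSE)
  out <- merge(full, df, by = c("region", "class"), all.x = TRUE)
  out$count[is.na(out$count)] <- 0L
  out[order(out$region, match(out$class, connection_classes())), ,
      drop = FALSE]
}

#' Percentage of reports per region within each connection class
#'
#' For each connection class k, `P_ck = 100 * N_ck / sum_c N_ck`: the
#' number of reports for region c as a percentage of the total reports
#' of that class. Within every class with any report the percentages
#' sum to 100; classes with no reports get `NA` and are flagged.
#'
#' @param counts A counts `data.frame` (see [read_connection_counts()]).
#' @return The table with a `P` column added; all-zero classes are
#'   listed in the `zero_classes` attribute.
#' @export
class_percentages <- function(counts) {
  totals <- tapply(counts$count, counts$class, sum)
  counts$P <- 100 * counts$count / as.numeric(totals[counts$class])
  zero <- names(totals)[totals == 0]
  counts$P[counts$class %in% zero] <- NA_real_
  attr(counts, "zero_classes") <- zero
  counts
}

#' Normalised proportion of reports per region
#'
#' `Pn_ck = 100 * P_ck / sum_k P_ck` over the four connection classes of
#' a region, balancing the overall over-reporting of afferents relative
#' to efferents: within each region with any report the normalised
#' proportions sum to 100. Regions with no reports in any class are
#' excluded and flagged.
#'
#' @param counts A table carrying a `P` column (see
#'   [class_percentages()]); `P` is computed first if absent.
#' @return The table with a `Pn` column; excluded regions are listed in
#'   the `excluded_regions` attribute.
#' @export
normalized_proportion <- function(counts) {
  if (is.null(counts$P)) counts <- class_percentages(counts)
  p <- counts$P
  p[is.na(p)] <- 0
  region_sum <- tapply(p, counts$region, sum)
  denom <- as.numeric(region_sum[counts$region])
  counts$Pn <- ifelse(denom > 0, 100 * p / denom, NA_real_)
  attr(counts, "excluded_regions") <- names(region_sum)[region_sum == 0]
  counts
}

#' Export a chord-diagram ribbon table
#'
#' Writes one ribbon row per (region, class) with a positive report
#' count: region, class, normalised proportion `Pn` (the ribbon width,
#' as a percentage) and a colour key — red for STN afferents, blue for
#' STN efferents, orange and light blue for the parasubthalamic
#' counterparts. The CSV is consumable by generic chord / ideogram
#' renderers.
#'
#' @param counts A counts table; `P` and `Pn` are computed if absent.
#' @param path Output CSV path.
#' @return The ribbon `data.frame`, invisibly.
#' @export
export_chord_table <- function(counts, path) {
  if (is.null(counts$Pn)) counts <- normalized_proportion(counts)
  colours <- stats::setNames(c("red", "blue", "orange", "lightblue"),
                             connection_classes())
  rib <- counts[counts$count > 0, c("region", "class", "Pn"), drop = FALSE]
  rib$colour <- colours[rib$class]
  rownames(rib) <- NULL
  utils::write.csv(rib, path, row.names = FALSE)
  invisible(rib)
}
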