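#' Embryo-to-oocyte methylation maintenance ratio
#'
#' For each feature the maintenance ratio is the embryo (or mole) methylation
#' divided by the germline methylation. Perfect maintenance of the maternal
#' allele in a diploid with an unmethylated paternal allele gives a ratio of
#' 0.5; complete loss gives 0; ratios above 1 (post-fertilisation gain) are
#' retained, not clipped. Features whose germline methylation is below
#' `cfg$maintenance_min_oocyte_pct` (20\%) are excluded: below that residual
#' level the ratio is dominated by noise.
#'
#' For paternally methylated classes, pass sperm as `germline`; the contract
#' is identical with the methylated germline in the denominator.
#'
#' @param germline feature methylation tibble of the germline (oocyte or
#'   sperm) methylome.
#' @param embryo feature methylation tibble of the embryo (or mole) over the
#'   same features.
#' @param cfg a [default_config()] list.
#' @param class label for the feature class (e.g. `"maternal_gDMR"`,
#'   `"maternal_domain"`); defaults to each feature's category.
#' @return a `maintenance_table` tibble: `name`, `class`, `germline_pct`,
#'   `embryo_pct`, `ratio`, keeping only features with both values present
#'   and germline methylation at or above the residual threshold.
#' @export
maintenance_ratio <- function(germline, embryo, cfg = default_config(),
                              class = NULL) {
  if (!setequal(germline$name, embryo$name))
    stop_mi("germline and embryo feature sets differ")
  shared <- unique(germline$name)
  g <- germline[match(shared, germline$name), ]
  e <- embryo[match(shared, embryo$name), ]
  out <- tibble(name = shared,
                class = class %||% g$category,
                germline_pct = g$meth_pct,
                embryo_pct = e$meth_pct)
  out <- filter(out, !is.na(.data$germline_pct) & !is.na(.data$embryo_pct))
  out <- filter(out, .data$germline_pct >= cfg$maintenance_min_oocyte_pct)
  out$ratio <- out$embryo_pct / out$germline_pct
  class(out) <- c("maintenance_table", class(tibble()))
  out
}

#' Per-class summary of maintenance ratios
#'
#' Ratios are summarised per feature class by the median (each feature counts
#' once regardless of size), with the interquartile range and n.
#'
#' @param table a `maintenance_table` from [maintenance_ratio()], possibly
#'   several classes bound together.
#' @return tibble with `class`, `median_ratio`, `q25`, `q75`, `n`.
#' @export
class_summary <- function(table) {
  if (nrow(table) == 0) {
    warn_mi("empty maintenance table; no classes to summarise")
    return(tibble(class = character(), median_ratio = numeric(),
                  q25 = numeric(), q75 = numeric(), n = integer()))
  }
  summarise(group_by(as_tibble(table), class = .data$class),
            median_ratio = stats::median(.data$ratio),
            q25 = unname(stats::quantile(.data$ratio, 0.25)),
            q75 = unname(stats::quantile(.data$ratio, 0.75)),
            n = dplyr::n(), .groups = "drop")
}
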