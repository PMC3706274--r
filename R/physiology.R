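#' Strain physiology tables and change arithmetic
#'
#' A physiology table records, per strain, the specific growth rate `mu`
#' (1/h), the specific xylose uptake rate `q_xylose` (mmol/gDCW/h) and the
#' product yields `y_xylitol`, `y_glycerol`, `y_acetate`, `y_etoh` (g/g),
#' each with a stated plus/minus uncertainty. Uncertainties are carried
#' along verbatim but not propagated through the change arithmetic.
#'
#' The packaged table `xylose_physiology()` holds the measured physiology
#' of six recombinant xylose-fermenting S. cerevisiae strains: two hosts
#' (CTY, INV) each carrying a wild-type (WT) fungal xylose pathway or a
#' pathway whose XR/XDH/XKS promoter strengths were optimized in the CTY
#' host (CTYp) or the INV host (INVp).
#'
#' @param path file path to a TSV with columns `strain`, `metric`, `value`,
#'   `uncertainty`.
#' @return A `data.frame` of class `"physiology_table"`.
#' @export
read_physiology_table <- function(path) {
  df <- read_tsv_raw(path)
  need <- c("strain", "metric", "value", "uncertainty")
  if (!all(need %in% names(df)))
    stop_format("physiology table must have columns ",
                paste(need, collapse = ", "))
  if (!is.numeric(df$value) || !is.numeric(df$uncertainty))
    stop_value("physiology values must be numeric")
  if (any(df$value < 0))
    stop_value("physiology point values must be nonnegative")
  structure(df, class = c("physiology_table", "data.frame"))
}

#' @rdname read_physiology_table
#' @param x a `physiology_table`.
#' @export
write_physiology_table <- function(x, path) {
  stopifnot(inherits(x, "physiology_table"))
  write_tsv_raw(as.data.frame(x), path)
  invisible(path)
}

#' @rdname read_physiology_table
#' @export
xylose_physiology <- function() {
  read_physiology_table(system.file("extdata", "xylose_strain_physiology.tsv",
                                    package = "repcons", mustWork = TRUE))
}

# half-away-from-zero rounding to whole units (base round() is half-to-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Percent change and fold change between physiology values
#'
#' `percent_change()` computes the signed relative change
#' `100 * (new - reference) / reference`, reported both unrounded and
#' rounded to the nearest whole percent with halves rounded away from zero
#' (so a -28.33% computed change is reported as -28). Negative means a
#' decrease in `new` relative to `reference`. `fold_change()` is the plain
#' ratio `new / reference`.
#'
#' @param reference baseline value, must be > 0.
#' @param new compared value, must be >= 0.
#' @return `percent_change()`: list with `percent` (rounded integer-valued)
#'   and `unrounded`; `fold_change()`: numeric ratio. Both vectorize.
#' @examples
#' percent_change(0.60, 0.43)$percent   # -28
#' fold_change(0.60, 0.16)              # 3.75
#' @export
percent_change <- function(reference, new) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop_value("`reference` must be positive")
  if (any(new < 0))
    stop_value("`new` must be nonnegative")
  raw <- 100 * (new - reference) / reference
  list(percent = round_half_away(raw), unrounded = raw)
}

#' @rdname percent_change
#' @export
fold_change <- function(new, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop_value("`reference` must be positive")
  if (any(new < 0))
    stop_value("`new` must be nonnegative")
  new / reference
}

#' @rdname percent_change
#' @param table a `physiology_table`.
#' @param metric one of the table's metric names, e.g. `"q_xylose"`.
#' @param from,to strain names; the change is computed from `from`
#'   (reference) to `to`.
#' @export
physiology_change <- function(table, metric, from, to) {
  stopifnot(inherits(table, "physiology_table"))
  pick <- function(strain) {
    v <- table$value[table$strain == strain & table$metric == metric]
    if (length(v) != 1)
      stop_input("no unique row for strain ", strain, ", metric ", metric)
    v
  }
  ref <- pick(from); new <- pick(to)
  pc <- percent_change(ref, new)
  list(metric = metric, from = from, to = to,
       reference = ref, new = new,
       percent = pc$percent, percent_unrounded = pc$unrounded,
       fold = fold_change(new, ref))
}
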