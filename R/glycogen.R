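# The glycogen computation chain: net glucose -> glucose equivalents ->
# hydrolysis-efficiency correction -> per-protein normalization, plus the
# derived enrichment summaries.

#' Glucose-equivalent constant
#'
#' Each glucose residue in glycogen has lost one water, so a mg of glycogen
#' corresponds to 1000 / (180.06 - 18.01) = 6.17 umol of glucose. The
#' reported value is rounded to two decimals, matching how the constant is
#' used throughout; `unrounded = TRUE` returns 6.1709...
#'
#' @param unrounded Return the full-precision value.
#' @return umol glucose per mg glycogen.
#' @examples
#' glucose_equivalent_constant()  # 6.17
#' @export
glucose_equivalent_constant <- function(unrounded = FALSE) {
  v <- 1000 / (180.06 - 18.01)
  if (unrounded) v else round(v, 2)
}

#' Net glucose released by hydrolysis
#'
#' Post-hydrolysis minus pre-hydrolysis free glucose. A negative result is
#' reported as-is with a warning flag, never clipped silently. A
#' pre-hydrolysis value below the limit of quantification may be passed as
#' `NA` with `pre_below_loq = TRUE`, in which case it is treated as zero and
#' flagged.
#'
#' @param post_nmol,pre_nmol Free glucose before/after hydrolysis (nmol).
#' @param pre_below_loq Set when the pre value was below LoQ.
#' @return Net glucose (nmol) with attributes `negative` and
#'   `pre_below_loq`.
#' @export
net_glucose <- function(post_nmol, pre_nmol, pre_below_loq = FALSE) {
  if (pre_below_loq || is.na(pre_nmol)) {
    if (!pre_below_loq)
      stop("pre_nmol is NA; set pre_below_loq = TRUE to treat it as 0")
    pre_nmol <- 0
  }
  net <- post_nmol - pre_nmol
  if (net < 0)
    warning("post-hydrolysis glucose below pre-hydrolysis glucose; ",
            "reporting negative net glucose")
  structure(net, negative = net < 0, pre_below_loq = pre_below_loq)
}

#' Glycogen content from net glucose
#'
#' `glycogen_ug = net_nmol / 6.17`, corrected for the hydrolysis efficiency
#' measured on a glycogen standard, and optionally normalized per mg
#' protein (or residue weight — the label records which was used).
#'
#' @param net_nmol Net glucose (nmol).
#' @param efficiency Hydrolysis efficiency fraction from the standard run;
#'   must be positive. Values above 1 (possible through measurement error,
#'   up to 1.2) are accepted with a warning.
#' @param protein_mg Optional normalizer mass (mg).
#' @param normalizer Label for the normalizer, `"protein"` or
#'   `"residue_weight"`.
#' @return List: `glycogen_ug`, `corrected_glycogen_ug`,
#'   `glycogen_per_mg` (NA when no normalizer), `normalizer`.
#' @examples
#' glycogen_from_glucose(111.4, 0.745)  # 18.1 ug -> 24.2 ug corrected
#' @export
glycogen_from_glucose <- function(net_nmol, efficiency, protein_mg = NULL,
                                  normalizer = c("protein",
                                                 "residue_weight")) {
  normalizer <- match.arg(normalizer)
  if (efficiency <= 0) stop("hydrolysis efficiency must be positive")
  if (efficiency > 1.2)
    stop("hydrolysis efficiency above 1.2 is not plausible")
  if (efficiency > 1)
    warning("hydrolysis efficiency above 1 (", round(efficiency, 3),
            "); accepted but check the standard run")
  gly <- net_nmol / glucose_equivalent_constant()
  corr <- gly / efficiency
  per <- if (!is.null(protein_mg)) {
    if (protein_mg <= 0) stop("protein_mg must be positive")
    corr / protein_mg
  } else NA_real_
  list(glycogen_ug = gly, corrected_glycogen_ug = corr,
       glycogen_per_mg = per, normalizer = normalizer)
}

#' Fractional enrichment as a percentage
#'
#' `100 * labeled / (labeled + unlabeled)`, reported at one decimal.
#'
#' @param labeled,unlabeled Amounts in consistent units.
#' @param digits Decimals to report (1 for tables, 0 for headline
#'   comparisons).
#' @return Percent.
#' @examples
#' fractional_enrichment(17.3, 21.1)  # 45.1
#' @export
fractional_enrichment <- function(labeled, unlabeled, digits = 1) {
  if (labeled < 0 || unlabeled < 0) stop("amounts must be non-negative")
  if (labeled + unlabeled <= 0)
    stop("undefined enrichment: both amounts are zero")
  round(100 * labeled / (labeled + unlabeled), digits)
}

#' NMR-visible fraction of total glycogen
#'
#' Solution NMR sees only the mobile, solvent-exposed glycogen branches;
#' hydrolysis-based quantification sees the whole granule. The ratio of the
#' pre-hydrolysis NMR value to the post-hydrolysis total, as a percentage
#' (nearest integer).
#'
#' @param nmr_visible Pre-hydrolysis NMR glycogen (ug/mg or ug).
#' @param total Post-hydrolysis total glycogen in the same units.
#' @return Percent, nearest integer.
#' @examples
#' nmr_visible_fraction(38.3, 44.8)  # 85
#' @export
nmr_visible_fraction <- function(nmr_visible, total) {
  if (total <= 0) stop("total glycogen must be positive")
  if (nmr_visible < 0) stop("nmr_visible must be non-negative")
  round(100 * nmr_visible / total)
}

#' Assemble a full glycogen report
#'
#' Combines pre/post-hydrolysis quantification into the complete chain plus
#' isotopologue splits (unlabeled / fully labeled / scrambled), fractional
#' enrichment, and — when an NMR pre-hydrolysis value is supplied — the
#' NMR-visible fraction.
#'
#' @param pre_nmol,post_nmol Pre-/post-hydrolysis free glucose (nmol).
#' @param efficiency Hydrolysis efficiency fraction.
#' @param protein_mg Normalizer mass (mg), optional.
#' @param fractions Optional named isotopologue fraction vector (post
#'   hydrolysis) over species labels; used for the splits.
#' @param tracer `"13C6"` or `"2H7"` — identifies the fully labeled species.
#' @param nmr_glycogen_ug_per_mg Optional NMR-visible glycogen in the same
#'   per-mg units as the report.
#' @param pre_below_loq Flag for a below-LoQ pre value.
#' @param normalizer Normalizer label, see [glycogen_from_glucose()].
#' @return Object of class `glycogen_report`.
#' @export
glycogen_report <- function(pre_nmol, post_nmol, efficiency,
                            protein_mg = NULL, fractions = NULL,
                            tracer = c("13C6", "2H7"),
                            nmr_glycogen_ug_per_mg = NULL,
                            pre_below_loq = FALSE,
                            normalizer = c("protein", "residue_weight")) {
  tracer <- match.arg(tracer)
  normalizer <- match.arg(normalizer)
  net <- net_glucose(post_nmol, pre_nmol, pre_below_loq)
  g <- glycogen_from_glucose(as.numeric(net), efficiency, protein_mg,
                             normalizer)
  split <- NULL
  enr_pct <- NA_real_
  if (!is.null(fractions)) {
    if (abs(sum(fractions) - 1) > 1e-6)
      stop("isotopologue fractions must sum to 1")
    full <- tracer  # label of the fully labeled species
    labs <- names(fractions)
    f_un <- sum(fractions[labs == "M+0"])
    f_full <- sum(fractions[labs == full])
    f_scr <- 1 - f_un - f_full
    split <- c(unlabeled = 100 * f_un, fully_labeled = 100 * f_full,
               scrambled = 100 * max(f_scr, 0))
    enr_pct <- fractional_enrichment(1 - f_un, f_un)
  }
  nmr_vis <- if (!is.null(nmr_glycogen_ug_per_mg) && !is.na(g$glycogen_per_mg))
    nmr_visible_fraction(nmr_glycogen_ug_per_mg, g$glycogen_per_mg)
  else NA_real_
  structure(list(pre_nmol = if (pre_below_loq) 0 else pre_nmol,
                 post_nmol = post_nmol,
                 net_nmol = as.numeric(net),
                 negative_net = attr(net, "negative"),
                 pre_below_loq = pre_below_loq,
                 efficiency = efficiency,
                 glycogen_ug = g$glycogen_ug,
                 corrected_glycogen_ug = g$corrected_glycogen_ug,
                 protein_mg = if (is.null(protein_mg)) NA_real_ else protein_mg,
                 glycogen_per_mg = g$glycogen_per_mg,
                 normalizer = normalizer,
                 tracer = tracer,
                 split_percent = split,
                 enrichment_percent = enr_pct,
                 nmr_visible_percent = nmr_vis),
            class = "glycogen_report")
}

#' @export
print.glycogen_report <- function(x, ...) {
  cat("<glycogen_report>\n")
  cat(sprintf("  Pre-hydrolysis glucose:   %.1f nmol%s\n", x$pre_nmol,
              if (x$pre_below_loq) " (<LoQ, treated as 0)" else ""))
  cat(sprintf("  Post-hydrolysis glucose:  %.1f nmol\n", x$post_nmol))
  cat(sprintf("  Net glucose:              %.1f nmol\n", x$net_nmol))
  cat(sprintf("  Glycogen:                 %.1f ug\n", x$glycogen_ug))
  cat(sprintf("  Hydrolysis efficiency:    %.1f %%\n", 100 * x$efficiency))
  cat(sprintf("  Corrected glycogen:       %.1f ug\n",
              x$corrected_glycogen_ug))
  if (!is.na(x$glycogen_per_mg))
    cat(sprintf("  Glycogen per mg %s: %.1f ug/mg\n", x$normalizer,
                x$glycogen_per_mg))
  if (!is.null(x$split_percent))
    cat(sprintf("  Split (%s): unlabeled %.1f%%, fully labeled %.1f%%, scrambled %.1f%%\n",
                x$tracer, x$split_percent[["unlabeled"]],
                x$split_percent[["fully_labeled"]],
                x$split_percent[["scrambled"]]))
  if (!is.na(x$enrichment_percent))
    cat(sprintf("  Fractional enrichment:    %.1f %%\n",
                x$enrichment_percent))
  if (!is.na(x$nmr_visible_percent))
    cat(sprintf("  NMR-visible glycogen:     %d %%\n",
                as.integer(x$nmr_visible_percent)))
  invisible(x)
}

#' @export
as.data.frame.glycogen_report <- function(x, ...) {
  data.frame(
    pre_hydrolysis_glucose_nmol = x$pre_nmol,
    post_hydrolysis_glucose_nmol = x$post_nmol,
    net_glucose_nmol = x$net_nmol,
    glycogen_ug = x$glycogen_ug,
    hydrolysis_efficiency_percent = 100 * x$efficiency,
    corrected_glycogen_ug = x$corrected_glycogen_ug,
    glycogen_per_mg = x$glycogen_per_mg,
    normalizer = x$normalizer,
    unlabeled_percent = if (is.null(x$split_percent)) NA_real_
                        else x$split_percent[["unlabeled"]],
    fully_labeled_percent = if (is.null(x$split_percent)) NA_real_
                            else x$split_percent[["fully_labeled"]],
    scrambled_percent = if (is.null(x$split_percent)) NA_real_
                        else x$split_percent[["scrambled"]],
    enrichment_percent = x$enrichment_percent,
    nmr_visible_percent = x$nmr_visible_percent)
}
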