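#' Relative gene expression by the 2^-ddCt method
#'
#' Per-sample fold change of a target gene relative to a calibrator group,
#' normalized against the geometric mean of multiple reference genes. On the
#' Ct scale the geometric mean of linear reference quantities is simply the
#' arithmetic mean of their Cts, which is the default normalizer; an
#' alternative averages the reference genes arithmetically on the linear scale
#' first. Technical replicate wells are averaged per sample and gene before
#' any differencing. Amplification efficiencies are carried through and, when
#' `efficiency_correction = TRUE`, replace the ideal doubling base:
#' fold = (1 + E)^-ddCt with E taken from the target gene.
#'
#' @param table data frame with columns `sample_id`, `group`, `gene`, `ct`
#'   (threshold cycles, positive), `is_reference` (logical), optional
#'   `efficiency_pct` (percent, in (50, 150)).
#' @param target target gene name.
#' @param calibrator_group group label used as the calibrator (its mean
#'   delta-Ct is subtracted, so its geometric-mean fold is 1).
#' @param ref_summary `"geometric"` (mean of reference Cts; default, the
#'   standard multi-reference normalization) or `"arithmetic"` (mean of linear
#'   reference quantities, logged back to the Ct scale).
#' @param efficiency_correction use per-gene efficiencies instead of the ideal
#'   base 2 (default `FALSE`, the plain 2^-ddCt model).
#' @return tibble with one row per sample: `sample_id`, `group`, `gene`,
#'   `ref_ct`, `delta_ct`, `delta_delta_ct`, `fold`.
#' @examples
#' tb <- tibble::tibble(
#'   sample_id = rep(c("s1", "s2"), each = 3),
#'   group = rep(c("wt", "ko"), each = 3),
#'   gene = rep(c("ef1a", "gapdh", "cck"), 2),
#'   ct = c(20, 22, 25, 20, 22, 26),
#'   is_reference = rep(c(TRUE, TRUE, FALSE), 2))
#' ddct(tb, target = "cck", calibrator_group = "wt")
#' @export
ddct <- function(table, target, calibrator_group,
                 ref_summary = c("geometric", "arithmetic"),
                 efficiency_correction = FALSE) {
  ref_summary <- match.arg(ref_summary)
  table <- tibble::as_tibble(table)
  needed <- c("sample_id", "group", "gene", "ct", "is_reference")
  if (!all(needed %in% names(table))) {
    stop("Ct table needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (any(table$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  if ("efficiency_pct" %in% names(table)) {
    eff <- table$efficiency_pct
    if (any(!is.na(eff) & (eff <= 50 | eff >= 150))) {
      stop("efficiencies must lie in (50, 150) percent", call. = FALSE)
    }
  }
  if (!target %in% table$gene) stop("target gene not in table", call. = FALSE)
  if (!calibrator_group %in% table$group) {
    stop("calibrator group is empty", call. = FALSE)
  }

  # technical replicates: one Ct per sample x gene
  wells <- dplyr::summarise(
    dplyr::group_by(table, .data$sample_id, .data$group, .data$gene,
                    .data$is_reference),
    ct = mean(.data$ct), .groups = "drop")

  samples <- unique(wells$sample_id)
  ref_ct <- vapply(samples, function(s) {
    refs <- wells[wells$sample_id == s & wells$is_reference, , drop = FALSE]
    if (nrow(refs) == 0) {
      stop("sample ", s, " has no reference genes", call. = FALSE)
    }
    if (ref_summary == "geometric") {
      mean(refs$ct)
    } else {
      -log2(mean(2^(-refs$ct)))
    }
  }, numeric(1))

  tgt <- wells[wells$gene == target & !wells$is_reference, , drop = FALSE]
  if (nrow(tgt) == 0) {
    tgt <- wells[wells$gene == target, , drop = FALSE]
  }
  miss <- setdiff(tgt$sample_id, samples)
  if (length(miss) > 0) {
    stop("sample ", paste(miss, collapse = ", "), " has no reference genes",
         call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = tgt$sample_id,
    group = tgt$group,
    gene = target,
    ref_ct = unname(ref_ct[match(tgt$sample_id, samples)]),
    delta_ct = tgt$ct - unname(ref_ct[match(tgt$sample_id, samples)])
  )
  cal <- out$delta_ct[out$group == calibrator_group]
  if (length(cal) == 0) stop("calibrator group is empty", call. = FALSE)
  out$delta_delta_ct <- out$delta_ct - mean(cal)

  base <- 2
  if (efficiency_correction) {
    if (!"efficiency_pct" %in% names(table)) {
      stop("`efficiency_correction = TRUE` needs an `efficiency_pct` column",
           call. = FALSE)
    }
    e_pct <- table$efficiency_pct[table$gene == target]
    e_pct <- e_pct[is.finite(e_pct)][1]
    if (!is.finite(e_pct)) {
      stop("no efficiency recorded for target gene", call. = FALSE)
    }
    base <- 1 + e_pct / 100
  }
  out$fold <- base^(-out$delta_delta_ct)
  out
}
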