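#' Relative gene expression by the comparative Ct method
#'
#' Computes 2^-ddCt fold changes for one target gene, normalized to a
#' housekeeping reference gene and calibrated to a control group:
#' per sample, `dCt = Ct_target - Ct_reference`; the calibrator is the
#' arithmetic mean dCt of the control-group samples; `ddCt = dCt -
#' calibrator`; the fold change is `2^-ddCt`.  Group summaries are the mean
#' and SD of the per-sample fold changes.
#'
#' Samples missing either Ct are excluded with a warning.  Adding any
#' constant to every Ct value (target and reference alike) leaves all fold
#' changes unchanged, and the geometric mean of control-group fold changes
#' is 1 by construction.
#'
#' @param ct Long-format data frame with columns `sample`, `group`, `gene`,
#'   `ct`: one row per (sample, gene) Ct measurement.
#' @param target_gene Gene to quantify.
#' @param reference_gene Housekeeping gene (e.g. `"GAPDH"`).
#' @param control_group Calibrator group label (e.g. the saline/vehicle
#'   group).
#' @return A list with `samples` (data frame: `sample`, `group`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change`), `groups` (data frame: `group`, `n`,
#'   `mean_fold`, `sd_fold`), and `calibrator` (mean control dCt).
#' @examples
#' ct <- simulate_ct(data.frame(label = c("saline", "treated"), n = c(3, 3),
#'                              log2_shift = c(0, 1)),
#'                   reference_sd = 0, seed = 1)
#' fold_change_ddct(ct, "target", "reference", "saline")$groups
#' @export
fold_change_ddct <- function(ct, target_gene, reference_gene, control_group) {
  need <- c("sample", "group", "gene", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("Ct table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!target_gene %in% ct$gene)
    stop(sprintf("target gene '%s' not present", target_gene), call. = FALSE)
  if (!reference_gene %in% ct$gene)
    stop(sprintf("reference gene '%s' not present", reference_gene),
         call. = FALSE)
  if (!control_group %in% ct$group)
    stop(sprintf("control group '%s' not present", control_group),
         call. = FALSE)

  tgt <- ct[ct$gene == target_gene, c("sample", "group", "ct")]
  ref <- ct[ct$gene == reference_gene, c("sample", "ct")]
  names(tgt)[3] <- "ct_target"
  names(ref)[2] <- "ct_reference"
  merged <- merge(tgt, ref, by = "sample", all.x = TRUE, sort = FALSE)
  incomplete <- !is.finite(merged$ct_target) | !is.finite(merged$ct_reference)
  if (any(incomplete)) {
    warning(sum(incomplete), " sample(s) excluded for missing target or ",
            "reference Ct", call. = FALSE)
    merged <- merged[!incomplete, , drop = FALSE]
  }
  if (!any(merged$group == control_group))
    stop("control group has no complete samples", call. = FALSE)

  merged$delta_ct <- merged$ct_target - merged$ct_reference
  calibrator <- mean(merged$delta_ct[merged$group == control_group])
  merged$delta_delta_ct <- merged$delta_ct - calibrator
  merged$fold_change <- 2^(-merged$delta_delta_ct)

  samples <- merged[, c("sample", "group", "delta_ct", "delta_delta_ct",
                        "fold_change")]
  rownames(samples) <- NULL
  grp_levels <- unique(merged$group)
  groups <- do.call(rbind, lapply(grp_levels, function(g) {
    f <- merged$fold_change[merged$group == g]
    data.frame(group = g, n = length(f), mean_fold = mean(f),
               sd_fold = if (length(f) > 1) stats::sd(f) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(samples = samples, groups = groups, calibrator = calibrator)
}
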