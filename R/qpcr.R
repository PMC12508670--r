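# Comparative 2^-DDCt quantification of qPCR Ct tables.

#' Relative gene expression by the comparative 2^-DDCt method
#'
#' Per sample and gene, technical replicates are averaged (arithmetic mean of
#' Ct). Each target gene is normalized to the housekeeping gene within the
#' same sample: `DCt = Ct(target) - Ct(housekeeping)`. With a single
#' housekeeping gene, normalizing to its geometric mean expression is exactly
#' subtraction of its mean Ct (geometric mean in expression space equals
#' arithmetic mean in the log2 Ct space). Then
#' `DDCt = DCt - mean DCt(reference condition)` and fold change = `2^-DDCt`,
#' so the reference condition's fold changes average (geometrically) to 1.
#'
#' @param ct_table A data frame with columns `sample`, `condition`, `gene`,
#'   `ct`, and optionally `replicate`. `ct` must be positive cycle counts.
#' @param housekeeping Housekeeping gene id (e.g. `"Rpl19"`); must be present
#'   in every sample.
#' @param reference_condition The condition fold changes are expressed
#'   against (e.g. `"control"`).
#' @return A tibble with one row per (sample, target gene): `sample`,
#'   `condition`, `gene`, `dct`, `ddct`, `fold`, `log2_fold`.
#' @examples
#' ct <- data.frame(
#'   sample = rep(c("c1", "t1"), each = 2),
#'   condition = rep(c("control", "treated"), each = 2),
#'   gene = rep(c("Lhb", "Rpl19"), 2),
#'   ct = c(25, 20, 23, 20)
#' )
#' ddct_fold_change(ct, "Rpl19", "control")  # treated fold = 4
#' @export
ddct_fold_change <- function(ct_table, housekeeping, reference_condition) {
  stopifnot(is.data.frame(ct_table))
  need <- c("sample", "condition", "gene", "ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss))
    stop("ct_table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(ct_table$ct) | ct_table$ct <= 0))
    stop("all Ct values must be positive and finite", call. = FALSE)
  if (!reference_condition %in% ct_table$condition)
    stop("reference condition '", reference_condition,
         "' not present", call. = FALSE)

  mean_ct <- ct_table |>
    dplyr::group_by(.data$sample, .data$condition, .data$gene) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")

  hk <- mean_ct |>
    dplyr::filter(.data$gene == housekeeping) |>
    dplyr::select("sample", hk_ct = "ct")
  no_hk <- setdiff(unique(mean_ct$sample), hk$sample)
  if (length(no_hk))
    stop("housekeeping gene '", housekeeping, "' missing for sample(s): ",
         paste(no_hk, collapse = ", "), call. = FALSE)

  dct <- mean_ct |>
    dplyr::filter(.data$gene != housekeeping) |>
    dplyr::inner_join(hk, by = "sample") |>
    dplyr::mutate(dct = .data$ct - .data$hk_ct)

  ref <- dct |>
    dplyr::filter(.data$condition == reference_condition) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(ref_dct = mean(.data$dct), .groups = "drop")

  dct |>
    dplyr::inner_join(ref, by = "gene") |>
    dplyr::mutate(ddct = .data$dct - .data$ref_dct,
                  fold = 2^(-.data$ddct),
                  log2_fold = -.data$ddct) |>
    dplyr::select("sample", "condition", "gene", "dct", "ddct",
                  "fold", "log2_fold") |>
    dplyr::arrange(.data$gene, .data$condition, .data$sample)
}

#' Read a Ct table from CSV
#'
#' Expects columns `sample`, `condition`, `gene`, `replicate`, `ct`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_ct_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample", "condition", "gene", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("Ct table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab
}
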