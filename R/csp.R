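# Chemical-shift perturbation mapping between two protein variants.
# Missing assignments propagate as NA, never imputed to zero: many of a
# destabilized mutant's peaks are unobservable, and zero-filling would
# fabricate agreement.

.check_shift_table <- function(tab, label) {
  need <- c("residue_number", "dHN_ppm", "dN_ppm", "dCA_ppm")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop(sprintf("shift table %s lacks columns: %s", label,
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(tab$residue_number))
    stop(sprintf("shift table %s has duplicated residue numbers", label))
  invisible(tab)
}

# Join two shift tables on residue number; warn on residue-name mismatch.
.join_shifts <- function(table_a, table_b) {
  .check_shift_table(table_a, "A"); .check_shift_table(table_b, "B")
  j <- merge(table_a, table_b, by = "residue_number",
             suffixes = c("_a", "_b"))
  if (all(c("residue_name_a", "residue_name_b") %in% names(j))) {
    bad <- !is.na(j$residue_name_a) & !is.na(j$residue_name_b) &
      j$residue_name_a != j$residue_name_b & j$residue_name_a != "X" &
      j$residue_name_b != "X"
    if (any(bad))
      warning(sprintf("residue name mismatch at %s",
                      paste(j$residue_number[bad], collapse = ", ")))
  }
  j[order(j$residue_number), , drop = FALSE]
}

#' Amide chemical-shift perturbation between two variants
#'
#' Per shared residue, the combined amide perturbation
#' delta_amide = sqrt(dHN^2 + (dN/5)^2), with the conventional 1/5 scaling
#' of the nitrogen dimension (fixed: it defines the statistic). Residues
#' lacking either amide shift in either table yield NA, never zero.
#'
#' @param table_a,table_b Shift tables (data frames with `residue_number`,
#'   `dHN_ppm`, `dN_ppm`, `dCA_ppm`).
#' @return Data frame with `residue`, `d_amide` (ppm, >= 0 or NA).
#' @examples
#' a <- data.frame(residue_number = 1, residue_name = "X",
#'                 dHN_ppm = 8.0, dN_ppm = 120, dCA_ppm = 56)
#' b <- transform(a, dHN_ppm = 8.1, dN_ppm = 120.5)
#' csp(a, b)$d_amide  # sqrt(0.1^2 + 0.1^2)
#' @export
csp <- function(table_a, table_b) {
  j <- .join_shifts(table_a, table_b)
  ok <- stats::complete.cases(j[, c("dHN_ppm_a", "dHN_ppm_b", "dN_ppm_a",
                                    "dN_ppm_b")])
  if (!any(ok)) stop("no shared residues with both amide shifts")
  d_hn <- j$dHN_ppm_a - j$dHN_ppm_b
  d_n <- j$dN_ppm_a - j$dN_ppm_b
  d <- sqrt(d_hn^2 + (d_n / 5)^2)
  d[!ok] <- NA_real_
  data.frame(residue = j$residue_number, d_amide = d)
}

#' Calpha shift differences and their cross-variant correlation
#'
#' Signed per-residue difference delta_CA(A) - delta_CA(B) plus the squared
#' Pearson correlation of the two Calpha shift sets; near-unity r^2
#' indicates a preserved secondary structure.
#'
#' @inheritParams csp
#' @return List with `diff` (data frame `residue`, `d_ca`) and `r2`
#'   (NA when fewer than 3 shared Calpha shifts).
#' @export
ca_diff <- function(table_a, table_b) {
  j <- .join_shifts(table_a, table_b)
  ok <- !is.na(j$dCA_ppm_a) & !is.na(j$dCA_ppm_b)
  d <- ifelse(ok, j$dCA_ppm_a - j$dCA_ppm_b, NA_real_)
  r2 <- if (sum(ok) >= 3)
    stats::cor(j$dCA_ppm_a[ok], j$dCA_ppm_b[ok])^2
  else NA_real_
  list(diff = data.frame(residue = j$residue_number, d_ca = d), r2 = r2)
}

#' Flag residues with large amide perturbations
#'
#' Strictly greater than the threshold (boundary values are not flagged);
#' residues with absent perturbations are never flagged.
#'
#' @param records Data frame from [csp()] (`residue`, `d_amide`).
#' @param threshold Perturbation threshold in ppm (> 0; default 0.15, the
#'   conventional cutoff for significant amide perturbation).
#' @return `records` with an added logical `above_threshold`.
#' @export
classify_csp <- function(records, threshold = 0.15) {
  stopifnot(is.data.frame(records), "d_amide" %in% names(records),
            threshold > 0)
  records$above_threshold <- !is.na(records$d_amide) &
    records$d_amide > threshold
  records
}

#' Write per-residue values into the B-factor column of a structure
#'
#' Every atom of a residue receives that residue's value; residues with no
#' (or NA) value receive the sentinel -1.00 so viewers can grey them out.
#' Residues are matched by number only (single chain assumed).
#'
#' @param values Data frame with `residue` and one numeric value column
#'   (the second column is used).
#' @param pdb A `bio3d` pdb object (see [read_structure()] or
#'   [bio3d::read.pdb()]).
#' @param file Optional output PDB path; when given, the annotated
#'   structure is written with fixed-width B-factors (%6.2f).
#' @return The annotated pdb object, invisibly when writing.
#' @export
map_to_structure <- function(values, pdb, file = NULL) {
  stopifnot(is.data.frame(values), ncol(values) >= 2,
            "residue" %in% names(values))
  val_col <- setdiff(names(values), "residue")[1]
  idx <- match(pdb$atom$resno, values$residue)
  if (all(is.na(idx))) stop("no overlapping residues between values and structure")
  b <- values[[val_col]][idx]
  b[is.na(b)] <- -1.00
  pdb$atom$b <- round(b, 2)
  if (!is.null(file)) {
    bio3d::write.pdb(pdb, file = file, b = pdb$atom$b)
    return(invisible(pdb))
  }
  pdb
}
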