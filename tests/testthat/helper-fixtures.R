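# Shared fixtures, built in code at test time.

# tiny labeled glomerulus with known pixel counts: 10x10 canvas,
# tuft = rows 3..8 x cols 3..8 (36 px), mesangial = rows 4..5 x cols 4..8
# (10 px), capsule ring on row 2
toy_glomerulus <- function(pixel_size_um = 0.25, lesion_type = "NOA",
                           cells = NULL) {
  mask <- matrix(0L, 10, 10)
  mask[3:8, 3:8] <- 2L
  mask[4:5, 4:8] <- 3L
  mask[2, 2:9] <- 1L
  cells <- cells %||% data.frame(
    cell_type = c(rep("mesangial", 4), rep("endothelial", 2), rep("podocyte", 2)),
    row = c(4, 4, 5, 5, 7, 7, 8, 8),
    col = c(4, 6, 4, 6, 3, 5, 3, 5),
    stringsAsFactors = FALSE
  )
  labeled_glomerulus(mask, cells, lesion_type, pixel_size_um)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force Dice by explicit pixel loop (independent oracle)
dice_bruteforce <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  inter <- 0L; sa <- 0L; sb <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j]) sa <- sa + 1L
      if (b[i, j]) sb <- sb + 1L
      if (a[i, j] && b[i, j]) inter <- inter + 1L
    }
  }
  if (sa + sb == 0) return(1)
  2 * inter / (sa + sb)
}

# brute-force Mann-Whitney U (pairwise comparison count, ties = 1/2)
u_bruteforce <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}

# kappa from first principles on a contingency table
kappa_from_table <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# one-row glomerulus morphometric record for table-level tests
glom_row <- function(lesion_type = "NOA", area = 20000, mf = 0.25,
                     n_mes = 60, n_end = 70, n_pod = 55,
                     patient_id = "P1", glom_id = "g1") {
  base <- data.frame(
    patient_id = patient_id, glom_id = glom_id, lesion_type = lesion_type,
    glomerular_area_um2 = area, mesangial_area_um2 = mf * area,
    mesangial_area_fraction = mf, n_mesangial = as.integer(n_mes),
    n_endothelial = as.integer(n_end), n_podocyte = as.integer(n_pod),
    stringsAsFactors = FALSE
  )
  cbind(base, glomRPS:::morpho_derive(base))
}
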