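# Synthetic labeled glomeruli: disc tuft + Bowman capsule ring + mesangial
# blobs + point cells. Emulates the annotated PAS glomerulus crops the
# downstream morphometrics consume; it makes no attempt at stain texture.

LESION_TYPES <- c("GS", "SS", "C", "KW", "NOA")
CELL_TYPES <- c("mesangial", "endothelial", "podocyte")

#' Mask label codes
#'
#' Label masks use the integer codes 0 = background, 1 = Bowman capsule ring,
#' 2 = tuft tissue, 3 = mesangial region (a subset of the tuft).
#' @export
MASK_CODES <- c(background = 0L, capsule = 1L, tuft = 2L, mesangial = 3L)

#' Specification of one synthetic glomerulus
#'
#' Defaults depend on the lesion type: Kimmelstiel-Wilson (KW) glomeruli get a
#' higher mesangial-fraction target, more mesangial cells and fewer podocytes
#' than "none of the above" (NOA) glomeruli; globally sclerosed (GS) glomeruli
#' are matrix-dominated with few resident cells.
#'
#' @param lesion_type one of `"GS"`, `"SS"`, `"C"`, `"KW"`, `"NOA"`.
#' @param tuft_radius_px positive integer tuft radius in pixels.
#' @param mesangial_fraction_target fraction of tuft pixels to label mesangial,
#'   in `[0, 1)`.
#' @param cell_counts named integer vector with exactly the names
#'   `mesangial`, `endothelial`, `podocyte`.
#' @param pixel_size_um physical pixel size in micrometres (0.25 matches a
#'   40x whole-slide scan).
#' @return an object of class `glomerulus_spec`.
#' @export
glomerulus_spec <- function(lesion_type = "NOA",
                            tuft_radius_px = 100L,
                            mesangial_fraction_target = NULL,
                            cell_counts = NULL,
                            pixel_size_um = 0.25) {
  lesion_type <- match.arg(lesion_type, LESION_TYPES)
  default_mf <- c(GS = 0.55, SS = 0.30, C = 0.25, KW = 0.40, NOA = 0.22)
  default_cells <- list(
    GS  = c(mesangial = 30L, endothelial = 20L, podocyte = 10L),
    SS  = c(mesangial = 60L, endothelial = 60L, podocyte = 45L),
    C   = c(mesangial = 55L, endothelial = 60L, podocyte = 40L),
    KW  = c(mesangial = 85L, endothelial = 75L, podocyte = 35L),
    NOA = c(mesangial = 55L, endothelial = 70L, podocyte = 60L)
  )
  mf <- mesangial_fraction_target %||% default_mf[[lesion_type]]
  cc <- cell_counts %||% default_cells[[lesion_type]]
  if (!is.numeric(mf) || length(mf) != 1L || mf < 0 || mf >= 1) {
    abort_glom("mesangial_fraction_target must be a single value in [0, 1)",
               "glomRPS_infeasible_spec")
  }
  if (!setequal(names(cc), CELL_TYPES)) {
    abort_glom("cell_counts must be named exactly {mesangial, endothelial, podocyte}",
               "glomRPS_bad_spec")
  }
  cc <- as.integer(cc[CELL_TYPES])
  names(cc) <- CELL_TYPES
  if (any(cc < 0)) abort_glom("cell_counts must be non-negative", "glomRPS_bad_spec")
  if (tuft_radius_px < 4) abort_glom("tuft_radius_px must be >= 4", "glomRPS_bad_spec")
  if (pixel_size_um <= 0) abort_glom("pixel_size_um must be positive", "glomRPS_bad_spec")
  structure(
    list(
      lesion_type = lesion_type,
      tuft_radius_px = as.integer(tuft_radius_px),
      mesangial_fraction_target = mf,
      cell_counts = cc,
      pixel_size_um = pixel_size_um
    ),
    class = "glomerulus_spec"
  )
}

#' Construct a labeled glomerulus object
#'
#' @param mask integer matrix with values in `MASK_CODES`.
#' @param cells data.frame with columns `cell_type`, `row`, `col` (1-based
#'   pixel coordinates of cell centroids, each on a tuft or mesangial pixel).
#' @param lesion_type lesion tag, one of `LESION_TYPES`.
#' @param pixel_size_um physical pixel size in micrometres.
#' @return an object of class `labeled_glomerulus`.
#' @export
labeled_glomerulus <- function(mask, cells, lesion_type, pixel_size_um = 0.25) {
  lesion_type <- match.arg(lesion_type, LESION_TYPES)
  mask <- validate_mask(mask)
  stopifnot(is.data.frame(cells),
            all(c("cell_type", "row", "col") %in% names(cells)))
  if (nrow(cells) > 0) {
    bad_type <- setdiff(unique(cells$cell_type), CELL_TYPES)
    if (length(bad_type)) {
      abort_glom(paste0("unknown cell type(s): ", paste(bad_type, collapse = ", ")),
                 "glomRPS_bad_cells")
    }
    on_tissue <- mask[cbind(cells$row, cells$col)] %in% c(2L, 3L)
    if (!all(on_tissue)) {
      abort_glom("every cell centroid must lie on a tuft or mesangial pixel",
                 "glomRPS_bad_cells")
    }
  }
  structure(
    list(mask = mask, cells = cells, lesion_type = lesion_type,
         pixel_size_um = pixel_size_um),
    class = "labeled_glomerulus"
  )
}

validate_mask <- function(mask) {
  if (!is.matrix(mask)) abort_glom("mask must be a matrix", "glomRPS_bad_mask")
  storage.mode(mask) <- "integer"
  bad <- setdiff(unique(as.vector(mask)), unname(MASK_CODES))
  if (length(bad)) {
    abort_glom(paste0("mask contains unknown label code(s): ",
                      paste(sort(bad), collapse = ", ")),
               "glomRPS_bad_mask")
  }
  mask
}

#' @export
print.labeled_glomerulus <- function(x, ...) {
  cat(sprintf("<labeled_glomerulus> %s, %dx%d px @ %.3g um/px, %d cells\n",
              x$lesion_type, nrow(x$mask), ncol(x$mask), x$pixel_size_um,
              nrow(x$cells)))
  invisible(x)
}

# squared distance from every pixel of an n x n canvas to (cr, cc)
.dist2_grid <- function(n, cr, cc) {
  outer((seq_len(n) - cr)^2, (seq_len(n) - cc)^2, `+`)
}

#' Generate a synthetic labeled glomerulus
#'
#' Renders a disc tuft surrounded by an annular Bowman capsule, grows random
#' mesangial blobs inside the tuft until the pixel count matches
#' `round(target * tuft pixels)` exactly, and rejection-samples point cells
#' (centroid + type) with a minimum centroid separation of 2 px. For lesion
#' type KW the first mesangial blob is a large nodule near the tuft centre.
#'
#' @param spec a [glomerulus_spec()].
#' @param seed integer seed; identical spec + seed gives an identical object.
#' @return a [labeled_glomerulus()].
#' @export
generate_glomerulus <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "glomerulus_spec"))
  with_seed(seed, {
    r <- spec$tuft_radius_px
    ring_gap <- max(2L, round(0.06 * r))
    ring_w <- max(2L, round(0.05 * r))
    margin <- 3L
    n <- 2L * (r + ring_gap + ring_w + margin) + 1L
    ctr <- (n + 1L) / 2
    d2 <- .dist2_grid(n, ctr, ctr)
    mask <- matrix(0L, n, n)
    mask[d2 <= (r + ring_gap + ring_w)^2 & d2 > (r + ring_gap)^2] <- 1L
    tuft <- d2 <= r^2
    mask[tuft] <- 2L

    tuft_idx <- which(tuft)
    n_tuft <- length(tuft_idx)
    target_px <- round(spec$mesangial_fraction_target * n_tuft)
    if (target_px > 0) {
      mes <- logical(length(mask))
      placed <- 0L
      add_blob <- function(center_idx, rad, need, nodular = FALSE) {
        cr <- ((center_idx - 1L) %% n) + 1L
        cc <- ((center_idx - 1L) %/% n) + 1L
        bd2 <- .dist2_grid(n, cr, cc)
        cand <- which(tuft & !mes & bd2 <= rad^2)
        if (length(cand) > need) {
          cand <- if (nodular) {
            cand[order(bd2[cand])[seq_len(need)]] # trim outside-in, keep blob compact
          } else {
            sample(cand, need)
          }
        }
        mes[cand] <<- TRUE
        length(cand)
      }
      if (spec$lesion_type == "KW") {
        off <- round(stats::runif(2, -0.35 * r, 0.35 * r))
        c_idx <- (ctr + off[2] - 1) * n + (ctr + off[1])
        placed <- placed + add_blob(as.integer(c_idx), max(3, 0.35 * r),
                                    target_px, nodular = TRUE)
      }
      guard <- 0L
      while (placed < target_px && guard < 10000L) {
        guard <- guard + 1L
        placed <- placed + add_blob(sample(tuft_idx, 1L),
                                    max(2, stats::runif(1, 0.08, 0.18) * r),
                                    target_px - placed)
      }
      if (placed < target_px) {
        abort_glom("could not reach mesangial fraction target", "glomRPS_infeasible_spec")
      }
      mask[mes] <- 3L
    }

    cells <- place_cells(mask, spec$cell_counts)
    labeled_glomerulus(mask, cells, spec$lesion_type, spec$pixel_size_um)
  })
}

# Greedy rejection sampling over shuffled tissue pixels; separation >= 2 px is
# equivalent to "no occupied pixel in the 3x3 neighbourhood".
place_cells <- function(mask, cell_counts) {
  n_total <- sum(cell_counts)
  tissue_idx <- which(mask == 2L | mask == 3L)
  nr <- nrow(mask)
  if (n_total == 0) {
    return(data.frame(cell_type = character(0), row = integer(0), col = integer(0),
                      stringsAsFactors = FALSE))
  }
  occ <- matrix(FALSE, nr, ncol(mask))
  order_idx <- sample(tissue_idx)
  rows <- integer(n_total); cols <- integer(n_total)
  k <- 0L
  for (idx in order_idx) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    if (any(occ[max(1L, r - 1L):min(nr, r + 1L),
                max(1L, c - 1L):min(ncol(mask), c + 1L)])) next
    k <- k + 1L
    occ[r, c] <- TRUE
    rows[k] <- r; cols[k] <- c
    if (k == n_total) break
  }
  if (k < n_total) {
    abort_glom(sprintf("cannot place %d cells: only %d sites at >= 2 px separation",
                       n_total, k), "glomRPS_infeasible_spec")
  }
  types <- rep(CELL_TYPES, times = cell_counts[CELL_TYPES])
  data.frame(cell_type = types, row = rows, col = cols, stringsAsFactors = FALSE)
}

#' Perturb one class of a label mask by a controlled amount
#'
#' Removes exactly `round(flip_fraction * s)` pixels of the target class
#' (where `s` is the class pixel count) and adds the same number of pixels
#' from successive border dilations, so the perturbed class keeps size `s` and
#' its Dice overlap with the original is `1 - flip_fraction` by construction.
#'
#' @param mask integer label mask.
#' @param flip_fraction fraction of class pixels to toggle, in `[0, 1]`.
#' @param seed integer seed.
#' @param class label code to perturb (default 3, the mesangial region).
#' @param fill code written over removed pixels (default 2, tuft).
#' @return a perturbed mask of the same shape.
#' @export
perturb_mask <- function(mask, flip_fraction, seed = 1L, class = 3L, fill = 2L) {
  mask <- validate_mask(mask)
  if (!is.numeric(flip_fraction) || flip_fraction < 0 || flip_fraction > 1) {
    abort_glom("flip_fraction must be in [0, 1]", "glomRPS_bad_spec")
  }
  s <- sum(mask == class)
  k <- round(flip_fraction * s)
  if (k == 0) return(mask)
  with_seed(seed, {
    out <- mask
    cls_idx <- which(mask == class)
    drop <- sample(cls_idx, k)
    out[drop] <- fill
    # collect k border pixels by repeated 4-neighbour dilation of the class
    current <- mask == class
    added <- integer(0)
    nr <- nrow(mask); nc <- ncol(mask)
    for (ring in seq_len(200L)) {
      if (length(added) >= k) break
      dil <- current
      dil[-1, ] <- dil[-1, ] | current[-nr, ]
      dil[-nr, ] <- dil[-nr, ] | current[-1, ]
      dil[, -1] <- dil[, -1] | current[, -nc]
      dil[, -nc] <- dil[, -nc] | current[, -1]
      border <- which(dil & !current)
      if (!length(border)) break
      take <- min(k - length(added), length(border))
      added <- c(added, sample(border, take))
      current <- dil
    }
    if (length(added) < k) {
      abort_glom("mask too small to absorb the requested perturbation",
                 "glomRPS_infeasible_spec")
    }
    out[added] <- class
    out
  })
}
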