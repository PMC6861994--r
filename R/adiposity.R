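#' Construct a CT slice object
#'
#' A single axial abdominal CT slice: a matrix of Hounsfield units, the
#' in-plane pixel spacing, and a logical mask marking pixels inside the
#' abdominal cavity (the visceral compartment). Separating visceral from
#' subcutaneous fat needs the abdominal-wall contour; this package takes it
#' as an input mask rather than segmenting it.
#'
#' @param hu Numeric matrix of Hounsfield units.
#' @param pixel_spacing Length-2 numeric, mm per pixel (row, col); both > 0.
#' @param visceral_mask Logical matrix, same shape as `hu`; `TRUE` inside
#'   the abdominal cavity.
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(hu, pixel_spacing, visceral_mask) {
  if (!is.matrix(hu) || !is.numeric(hu)) {
    stop("hu must be a numeric matrix", call. = FALSE)
  }
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (length(pixel_spacing) != 2 || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0)) {
    stop("pixel_spacing must be two positive numbers (mm)", call. = FALSE)
  }
  if (!is.matrix(visceral_mask) || !is.logical(visceral_mask) ||
      !identical(dim(visceral_mask), dim(hu))) {
    stop("visceral_mask must be a logical matrix with the same shape as hu",
         call. = FALSE)
  }
  structure(
    list(hu = hu, pixel_spacing = pixel_spacing, visceral_mask = visceral_mask),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, spacing %.3g x %.3g mm\n",
              nrow(x$hu), ncol(x$hu), x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}

#' Adipose-tissue mask by Hounsfield-unit windowing
#'
#' Marks pixels whose attenuation falls within the adipose window, -250 to
#' -50 HU, inclusive at both boundaries.
#'
#' @param slice A [ct_slice()].
#' @param hu_window Length-2 numeric window (low, high); default
#'   `c(-250, -50)`.
#' @return Logical matrix, `TRUE` on adipose pixels.
#' @export
adipose_mask <- function(slice, hu_window = default_config()$adiposity$hu_window) {
  stopifnot(inherits(slice, "ct_slice"))
  slice$hu >= hu_window[1] & slice$hu <= hu_window[2]
}

#' Visceral and subcutaneous adipose areas from a CT slice
#'
#' Counts adipose pixels ([adipose_mask()]) inside and outside the visceral
#' compartment and converts counts to cm2 via the pixel area
#' (spacing_row x spacing_col mm2 / 100). Visceral obesity is flagged at
#' VAT >= 100 cm2 (inclusive). `fat_ratio` is VAT/SAT (NA when SAT is 0).
#'
#' @inheritParams adipose_mask
#' @param vat_obesity_cm2 Visceral-obesity threshold; default 100.
#' @return One-row tibble: `vat_cm2`, `sat_cm2`, `total_cm2`, `fat_ratio`,
#'   `visceral_obese`.
#' @export
#' @examples
#' ph <- make_phantom(vat_cm2 = 150, sat_cm2 = 220, spacing = 2, seed = 1)
#' fat_areas(ph)
fat_areas <- function(slice, hu_window = default_config()$adiposity$hu_window,
                      vat_obesity_cm2 = default_config()$adiposity$vat_obesity_cm2) {
  stopifnot(inherits(slice, "ct_slice"))
  fat <- adipose_mask(slice, hu_window)
  px_cm2 <- prod(slice$pixel_spacing) / 100
  vat <- sum(fat & slice$visceral_mask) * px_cm2
  sat <- sum(fat & !slice$visceral_mask) * px_cm2
  tibble::tibble(
    vat_cm2 = vat, sat_cm2 = sat, total_cm2 = vat + sat,
    fat_ratio = ifelse(sat > 0, vat / sat, NA_real_),
    visceral_obese = vat >= vat_obesity_cm2
  )
}

#' Synthetic CT slice with known adipose areas
#'
#' Builds a phantom slice whose visceral and subcutaneous adipose areas
#' equal the requested targets after pixel quantization: targets are
#' rounded to the nearest whole number of pixels (with a message when the
#' target is not exactly representable). Adipose pixels (-90 HU) are placed
#' at seeded random positions, visceral fat inside a central disk and
#' subcutaneous fat in an outer ring; remaining pixels are soft tissue
#' (40 HU) inside the body and air (-1000 HU) outside.
#'
#' @param vat_cm2,sat_cm2 Target areas, cm2 (>= 0).
#' @param spacing Pixel spacing, mm (scalar or length 2); default 2.
#' @param dim Grid dimension in pixels (square); default 256. Must be large
#'   enough to hold the requested pixel counts.
#' @param seed Integer seed for the placement RNG (local; does not disturb
#'   the global RNG state).
#' @return A [ct_slice()] whose [fat_areas()] recover the (quantized)
#'   targets exactly.
#' @export
make_phantom <- function(vat_cm2, sat_cm2, spacing = 2, dim = 256L, seed = 1L) {
  if (vat_cm2 < 0 || sat_cm2 < 0) stop("targets must be >= 0", call. = FALSE)
  spacing <- if (length(spacing) == 1) rep(spacing, 2) else as.numeric(spacing)
  px_cm2 <- prod(spacing) / 100
  n_vat <- round(vat_cm2 / px_cm2)
  n_sat <- round(sat_cm2 / px_cm2)
  if (abs(n_vat * px_cm2 - vat_cm2) > 1e-9 || abs(n_sat * px_cm2 - sat_cm2) > 1e-9) {
    message(sprintf(
      "targets quantized to pixel grid: vat %.4f cm2, sat %.4f cm2",
      n_vat * px_cm2, n_sat * px_cm2))
  }
  nr <- nc <- as.integer(dim)
  cx <- (nr + 1) / 2
  cy <- (nc + 1) / 2
  rr <- outer(seq_len(nr), seq_len(nc), function(i, j) sqrt((i - cx)^2 + (j - cy)^2))
  body <- rr <= 0.48 * nr
  visceral <- rr <= 0.30 * nr
  subcut <- body & !visceral
  if (n_vat > sum(visceral) || n_sat > sum(subcut)) {
    stop("targets too large for the grid; increase dim or spacing",
         call. = FALSE)
  }
  hu <- matrix(-1000, nr, nc)
  hu[body] <- 40
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  vat_px <- sample(which(visceral), n_vat)
  sat_px <- sample(which(subcut), n_sat)
  hu[vat_px] <- -90
  hu[sat_px] <- -90
  ct_slice(hu, spacing, visceral)
}

#' Write / read a CT slice as plain text
#'
#' The HU grid and the visceral mask are written as headerless CSV grids,
#' with a JSON sidecar holding the pixel spacing. `path` is a prefix:
#' `<path>_hu.csv`, `<path>_mask.csv`, `<path>_meta.json`.
#'
#' @param slice A [ct_slice()].
#' @param path File-path prefix.
#' @return `write_ct_slice`: `path`, invisibly. `read_ct_slice`: a
#'   [ct_slice()].
#' @export
write_ct_slice <- function(slice, path) {
  stopifnot(inherits(slice, "ct_slice"))
  utils::write.table(slice$hu, paste0(path, "_hu.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(slice$visceral_mask * 1L, paste0(path, "_mask.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(pixel_spacing = slice$pixel_spacing),
                       paste0(path, "_meta.json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_ct_slice
#' @export
read_ct_slice <- function(path) {
  hu <- as.matrix(utils::read.csv(paste0(path, "_hu.csv"), header = FALSE))
  mask <- as.matrix(utils::read.csv(paste0(path, "_mask.csv"), header = FALSE)) == 1
  meta <- jsonlite::read_json(paste0(path, "_meta.json"), simplifyVector = TRUE)
  dimnames(hu) <- NULL
  dimnames(mask) <- NULL
  ct_slice(hu, meta$pixel_spacing, mask)
}
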