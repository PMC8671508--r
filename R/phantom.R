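## Digital phantom: nested-ellipsoid brain-like label grid with 0.055 T
## tissue parameters. Geometry is analytic (point-in-ellipsoid per voxel) so
## tests can check voxel counts against brute-force enumeration.

#' Default tissue parameters at 0.055 T
#'
#' Gray and white matter use the apparent relaxation estimates at 0.055 T
#' (GM T1/T2 = 330/110 ms, WM = 260/100 ms). CSF is assigned T1 = 4000 ms and
#' T2 = 2000 ms — comfortably beyond its lower bounds at this field
#' (T1 > 1500 ms, T2 > 1000 ms) so that short-TR saturation produces visible
#' FLAIR-like suppression. Proton densities (CSF 1.0, GM 0.9, WM 0.8) and
#' ADCs (GM 0.8e-3, WM 0.7e-3, CSF 3.0e-3 mm^2/s) follow standard
#' brain-phantom convention.
#'
#' @return data.frame with columns `name`, `pd`, `t1` (ms), `t2` (ms),
#'   `adc` (mm^2/s); row `i + 1` parameterizes label `i`, label 0 being
#'   background with zero proton density.
#' @examples
#' tt <- defaultTissues()
#' tt[tt$name == "GM", c("t1", "t2")]
#' @export
defaultTissues <- function() {
  data.frame(
    name = c("background", "CSF", "GM", "WM", "lesion"),
    pd   = c(0,    1.0,   0.9,   0.8,   0.95),
    t1   = c(1,    4000,  330,   260,   400),
    t2   = c(1,    2000,  110,   100,   250),
    adc  = c(0,    3.0e-3, 0.8e-3, 0.7e-3, 1.1e-3),
    stringsAsFactors = FALSE)
}

## normalized ellipsoid radius^2 of every voxel, semi-axes in voxel units
.ellipsoidR2 <- function(dims, center, semi) {
  x <- (seq_len(dims[1L]) - center[1L]) / semi[1L]
  y <- (seq_len(dims[2L]) - center[2L]) / semi[2L]
  z <- (seq_len(dims[3L]) - center[3L]) / semi[3L]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

#' Construct a brain-like labelled phantom
#'
#' Builds a concentric-ellipsoid "CSF shell - GM shell - WM core" layout
#' (outermost space is background), with an optional spherical lesion and an
#' optional smooth off-resonance field map. The geometry is a pure function
#' of its arguments; `seed` only drives the (optional) field-map
#' coefficients.
#'
#' @param gridShape integer length-3 label-grid dimensions; a length-2 value
#'   is treated as a single slice.
#' @param voxelSize numeric length-3 voxel size in mm.
#' @param tissues tissue table as from [defaultTissues()].
#' @param layout `"brain"` for the nested-ellipsoid layout or `"uniform"`
#'   to fill the whole grid with `uniformTissue`.
#' @param uniformTissue tissue name used when `layout = "uniform"`.
#' @param lesionSpec `NULL` or list `(center, radius)` in voxel units;
#'   voxels within `radius` of `center` get the `"lesion"` label. The full
#'   sphere must lie inside the grid.
#' @param fieldMapHz peak off-resonance amplitude in Hz; 0 disables the
#'   field map. The map is a smooth seeded quadratic-plus-linear surface.
#' @param seed RNG seed (field-map coefficients only).
#' @return a [Phantom-class].
#' @examples
#' ph <- makePhantom(c(64, 64, 1))
#' table(phantomLabels(ph))
#' @export
makePhantom <- function(gridShape = c(64L, 64L, 1L),
                        voxelSize = c(2, 2, 10),
                        tissues = defaultTissues(),
                        layout = c("brain", "uniform"),
                        uniformTissue = "GM",
                        lesionSpec = NULL,
                        fieldMapHz = 0,
                        seed = 1L) {
  layout <- match.arg(layout)
  gridShape <- as.integer(gridShape)
  if (length(gridShape) == 2L) gridShape <- c(gridShape, 1L)
  stopifnot(length(gridShape) == 3L, all(gridShape >= 1L))

  labs <- array(0L, dim = gridShape)
  lab <- function(name) match(name, tissues$name) - 1L

  if (layout == "uniform") {
    labs[] <- lab(uniformTissue)
  } else {
    center <- (gridShape + 1) / 2
    ## semi-axes as fractions of the half-extent per axis; a singleton axis
    ## degenerates gracefully (its term is 0 at the center plane)
    half <- pmax(gridShape / 2, 0.5)
    shells <- list(CSF = 0.90, GM = 0.80, WM = 0.55)
    r2csf <- .ellipsoidR2(gridShape, center, half * shells$CSF)
    r2gm  <- .ellipsoidR2(gridShape, center, half * shells$GM)
    r2wm  <- .ellipsoidR2(gridShape, center, half * shells$WM)
    labs[r2csf <= 1] <- lab("CSF")
    labs[r2gm  <= 1] <- lab("GM")
    labs[r2wm  <= 1] <- lab("WM")
  }

  if (!is.null(lesionSpec)) {
    ctr <- lesionSpec$center
    rad <- lesionSpec$radius
    stopifnot(length(ctr) == 3L, length(rad) == 1L, rad > 0)
    chk <- gridShape > 1L   # singleton axes (2D slices) impose no bound
    if (any((ctr - rad)[chk] < 1) || any((ctr + rad)[chk] > gridShape[chk]))
      stop("lesion extends outside the phantom grid")
    r2 <- .ellipsoidR2(gridShape, ctr, rep(rad, 3L))
    labs[r2 <= 1] <- lab("lesion")
  }

  fm <- NULL
  if (fieldMapHz > 0) {
    set.seed(stageSeed(seed, "phantom"))
    cf <- stats::runif(5L, -1, 1)
    x <- (seq_len(gridShape[1L]) - (gridShape[1L] + 1) / 2) / max(gridShape[1L] / 2, 0.5)
    y <- (seq_len(gridShape[2L]) - (gridShape[2L] + 1) / 2) / max(gridShape[2L] / 2, 0.5)
    surf <- cf[1L] * outer(x, y^0) + cf[2L] * outer(x^0, y) +
      cf[3L] * outer(x^2, y^0) + cf[4L] * outer(x^0, y^2) + cf[5L] * outer(x, y)
    surf <- surf / max(abs(surf)) * fieldMapHz
    fm <- array(rep(surf, gridShape[3L]), dim = gridShape)
  }

  new("Phantom", labels = labs, tissues = tissues,
      voxelSize = as.numeric(voxelSize), fieldMap = fm)
}

#' @describeIn makePhantom label-grid accessor.
#' @param object,x a `Phantom`.
#' @export
phantomLabels <- function(object) object@labels

#' @describeIn makePhantom tissue-table accessor.
#' @export
tissueTable <- function(object) object@tissues

#' @describeIn makePhantom voxel size in mm.
#' @export
voxelSize <- function(object) object@voxelSize

#' @describeIn makePhantom off-resonance map accessor (Hz or `NULL`).
#' @export
fieldMap <- function(object) object@fieldMap

#' Per-voxel map of one tissue parameter
#'
#' @param phantom a [Phantom-class].
#' @param param one of `"pd"`, `"t1"`, `"t2"`, `"adc"`.
#' @return numeric array shaped like the label grid.
#' @export
tissueParameterMap <- function(phantom, param = c("pd", "t1", "t2", "adc")) {
  param <- match.arg(param)
  vals <- phantom@tissues[[param]][as.integer(phantom@labels) + 1L]
  array(vals, dim = dim(phantom@labels))
}

setMethod("show", "Phantom", function(object) {
  d <- dim(object@labels)
  cnt <- table(factor(as.integer(object@labels),
                      levels = seq_len(nrow(object@tissues)) - 1L,
                      labels = object@tissues$name))
  cat(sprintf("Phantom: %d x %d x %d grid, voxel %.3g x %.3g x %.3g mm\n",
              d[1L], d[2L], d[3L],
              object@voxelSize[1L], object@voxelSize[2L], object@voxelSize[3L]))
  cat("  voxels:", paste(sprintf("%s=%d", names(cnt), as.integer(cnt)),
                         collapse = ", "), "\n")
  cat("  field map:", if (is.null(object@fieldMap)) "none" else
    sprintf("range [%.3g, %.3g] Hz", min(object@fieldMap), max(object@fieldMap)), "\n")
})

#' Export a phantom's label grid as NIfTI
#'
#' @param phantom a [Phantom-class].
#' @param path output `.nii`/`.nii.gz` path.
#' @return the path, invisibly.
#' @export
writePhantomNifti <- function(phantom, path) {
  img <- RNifti::asNifti(array(as.numeric(phantom@labels), dim(phantom@labels)),
                         pixdim = phantom@voxelSize)
  RNifti::writeNifti(img, path)
  invisible(path)
}
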