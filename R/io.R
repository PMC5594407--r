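## File formats
##
## Field container: a NIfTI volume of shape G1 x G2 x C (C = channels) plus
## a JSON sidecar `<path>.json` recording the channel layout
## ("tensor2: Mxx,Mxy,Myy" or "odf_fourier: a0,a2,b2,...") and the domain
## ([0,1]^2, node-centered grid). Fiber files: tab-delimited text with a
## header line `fiber_id point_index x y`, full double precision.

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Write a tensor or ODF field to a NIfTI volume with JSON sidecar
#'
#' @param field a [bt_tensor_field()] or [bt_odf_field()].
#' @param path output path (`.nii` / `.nii.gz`); the sidecar is written next
#'   to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  if (inherits(field, "bt_tensor_field")) {
    arr <- array(0, c(field$g1, field$g2, 3))
    arr[, , 1] <- field$M$xx; arr[, , 2] <- field$M$xy; arr[, , 3] <- field$M$yy
    meta <- list(format_version = 1L, kind = "tensor2",
                 channels = c("Mxx", "Mxy", "Myy"),
                 grid = c(field$g1, field$g2),
                 domain = "unit square, node-centered: node (i,j) at ((i-1/2)/G1,(j-1/2)/G2)")
  } else if (inherits(field, "bt_odf_field")) {
    arr <- field$coef
    orders <- odf_orders(field$L)
    meta <- list(format_version = 1L, kind = "odf_fourier",
                 channels = c("a0", as.vector(rbind(paste0("a", orders),
                                                    paste0("b", orders)))),
                 L = field$L, grid = c(field$g1, field$g2),
                 domain = "unit square, node-centered: node (i,j) at ((i-1/2)/G1,(j-1/2)/G2)")
  } else stop("field must be a bt_tensor_field or bt_odf_field")
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tensor or ODF field written by [write_field()]
#'
#' @param path path to the NIfTI volume; the JSON sidecar must sit next to it.
#' @return a [bt_tensor_field()] or [bt_odf_field()], per the sidecar `kind`.
#' @export
read_field <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing JSON sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  arr <- array(as.numeric(RNifti::readNifti(path)),
               dim = dim(RNifti::readNifti(path)))
  if (identical(meta$kind, "tensor2")) {
    if (dim(arr)[3] != 3L) stop("tensor2 volume must have 3 channels")
    bt_tensor_field(arr)
  } else if (identical(meta$kind, "odf_fourier")) {
    bt_odf_field(coefficients = arr, L = meta$L)
  } else stop("unknown field kind in sidecar: ", meta$kind)
}

#' Write fiber curves to a delimited text file
#'
#' Tab-separated columns `fiber_id`, `point_index`, `x`, `y` with a header
#' line; coordinates serialized at full double precision.
#'
#' @param fibers a [bt_curve()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fibers <- function(fibers, path) {
  if (inherits(fibers, "bt_curve")) fibers <- list(fibers)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("fiber_id\tpoint_index\tx\ty", con)
  for (k in seq_along(fibers)) {
    p <- unclass(fibers[[k]])
    writeLines(sprintf("%d\t%d\t%.17g\t%.17g", k, seq_len(nrow(p)),
                       p[, 1], p[, 2]), con)
  }
  invisible(path)
}

#' Read fiber curves from a delimited text file
#'
#' @param path path to a file written in the [write_fibers()] format.
#' @return list of [bt_curve()], in order of first appearance of `fiber_id`;
#'   points ordered by `point_index`.
#' @export
read_fibers <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = c("integer", "integer", "numeric", "numeric")),
    error = function(e) stop("malformed fiber file '", path, "': ",
                             conditionMessage(e)))
  need <- c("fiber_id", "point_index", "x", "y")
  if (!all(need %in% names(df)))
    stop("malformed fiber file '", path, "': header must name ",
         paste(need, collapse = ", "))
  if (anyNA(df)) {
    bad <- which(!stats::complete.cases(df))[1]
    stop("malformed fiber file '", path, "': non-numeric or missing value at record ", bad)
  }
  ids <- unique(df$fiber_id)
  lapply(ids, function(id) {
    sub <- df[df$fiber_id == id, ]
    sub <- sub[order(sub$point_index), ]
    bt_curve(cbind(sub$x, sub$y))
  })
}
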