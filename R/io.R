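# Minimal NIfTI-1 I/O (uncompressed .nii, little-endian, uint8 or float32).
# No NIfTI package ships with the target environment, and only the subset
# this package writes needs to be read back.

#' Write a 3D array as NIfTI-1
#'
#' Logical arrays are written as uint8 masks, numeric arrays as float32
#' (e.g. dose in Gy). Uncompressed single-file `.nii`, little-endian.
#'
#' @param x 3D logical or numeric array.
#' @param path output file path.
#' @param geometry an [image_geometry()] supplying voxel spacing/origin.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, geometry) {
  d <- dim(x)
  if (length(d) != 3L) stop("write_nifti expects a 3D array")
  is_mask <- is.logical(x)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(348L, 4)                      # sizeof_hdr
  writeBin(raw(36), con)           # data_type..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)  # dim[8]
  writeBin(raw(14), con)           # intent_p1..intent_code
  wi(if (is_mask) 2L else 16L, 2)  # datatype uint8 / float32
  wi(if (is_mask) 8L else 32L, 2)  # bitpix
  wi(0L, 2)                        # slice_start
  wf(c(1, geometry$spacing, 0, 0, 0, 0))  # pixdim[8]
  wf(352)                          # vox_offset
  wf(c(1, 0))                      # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con) # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                   # cal_max, cal_min, slice_duration
  wf(0)                            # toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  writeBin(raw(104), con)          # descrip, aux_file
  wi(c(0L, 1L), 2)                 # qform_code, sform_code = 1
  wf(rep(0, 6))                    # quatern b,c,d + qoffset x,y,z
  wf(c(geometry$spacing[1], 0, 0, geometry$origin[1]))  # srow_x
  wf(c(0, geometry$spacing[2], 0, geometry$origin[2]))  # srow_y
  wf(c(0, 0, geometry$spacing[3], geometry$origin[3]))  # srow_z
  writeBin(raw(16), con)           # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  writeBin(raw(4), con)            # extension flag
  if (is_mask) {
    writeBin(as.raw(as.integer(x)), con)
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#'
#' Supports uncompressed little-endian `.nii` with uint8 or float32 data.
#'
#' @param path file path.
#' @return List with `data` (3D array), `spacing`, `origin`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != 348L) stop("not a little-endian NIfTI-1 file")
  invisible(readBin(con, "raw", 36))
  dims <- readBin(con, "integer", 8, size = 2, endian = "little")
  invisible(readBin(con, "raw", 14))
  datatype <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 2 + 2))
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = "little")
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = "little")
  invisible(readBin(con, "raw", 8 + 2 + 2 + 12 + 4 + 8 + 104 + 4))
  invisible(readBin(con, "numeric", 6, size = 4, endian = "little"))
  srow <- matrix(readBin(con, "numeric", 12, size = 4, endian = "little"),
                 3, 4, byrow = TRUE)
  d <- dims[2:4]
  n <- prod(d)
  seek(con, vox_offset)
  data <- if (datatype == 2L) {
    array(as.integer(readBin(con, "raw", n)) > 0L, d)
  } else if (datatype == 16L) {
    array(readBin(con, "numeric", n, size = 4, endian = "little"), d)
  } else {
    stop("unsupported NIfTI datatype: ", datatype)
  }
  list(data = data, spacing = pixdim[2:4], origin = srow[, 4])
}

#' Write a structure set to a directory
#'
#' One NIfTI mask per structure plus a JSON manifest with the names,
#' geometry and landmark record.
#'
#' @param structures a `structure_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_structure_set <- function(structures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_masks <- c(structures$masks, structures$extras)
  for (nm in names(all_masks))
    write_nifti(all_masks[[nm]], file.path(dir, paste0(nm, ".nii")),
                structures$geometry)
  manifest <- list(structures = names(structures$masks),
                   extras = names(structures$extras),
                   geometry = list(shape = structures$geometry$shape,
                                   spacing = structures$geometry$spacing,
                                   origin = structures$geometry$origin),
                   landmarks = structures$landmarks,
                   spec = if (is.null(structures$spec)) NULL
                          else unclass(structures$spec))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a structure set written by [write_structure_set()]
#' @param dir directory containing the masks and `manifest.json`.
#' @return A `structure_set`.
#' @export
read_structure_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  g <- manifest$geometry
  geom <- image_geometry(g$shape, g$spacing, g$origin)
  rd <- function(nm) {
    v <- read_nifti(file.path(dir, paste0(nm, ".nii")))$data
    dim(v) <- geom$shape
    v
  }
  masks <- lapply(manifest$structures, rd)
  names(masks) <- manifest$structures
  extras <- list()
  for (nm in manifest$extras) extras[[nm]] <- rd(nm)
  spec <- manifest$spec
  if (!is.null(spec)) class(spec) <- "phantom_spec"
  structure(list(geometry = geom, masks = masks, extras = extras,
                 landmarks = manifest$landmarks, spec = spec),
            class = "structure_set")
}

# run-length encode a logical matrix column-major (JSON-friendly)
rle_encode <- function(px) {
  r <- rle(as.logical(as.vector(px)))
  list(dim = dim(px), first = r$values[1], lengths = r$lengths)
}

rle_decode <- function(enc) {
  vals <- rep(c(enc$first, !enc$first), length.out = length(enc$lengths))
  v <- rep(vals, enc$lengths)
  matrix(v, enc$dim[1], enc$dim[2])
}

beam_to_list <- function(b) {
  list(id = b$id, gantry_angle = b$gantry_angle, mu = b$mu,
       parent_id = b$parent_id,
       aperture = c(rle_encode(b$aperture$pixels),
                    list(pixel_spacing = b$aperture$pixel_spacing,
                         u_axis = b$aperture$u_axis,
                         u_flip = b$aperture$u_flip)))
}

beam_from_list <- function(l) {
  ap <- bev_image(l$gantry_angle, rle_decode(l$aperture),
                  l$aperture$pixel_spacing, l$aperture$u_axis,
                  l$aperture$u_flip)
  rt_beam(l$id, l$gantry_angle, ap, l$mu, l$parent_id)
}

#' Serialize / restore a plan as JSON
#'
#' Apertures are stored run-length encoded with their spacing and angle;
#' the round trip reproduces the plan bit-exactly.
#'
#' @param plan an `rt_plan`.
#' @param path output (input) file path.
#' @return `write_plan_json`: `path` invisibly; `read_plan_json`: the plan.
#' @export
write_plan_json <- function(plan, path) {
  obj <- list(technique = plan$technique, rx = plan$rx,
              beams = lapply(unname(plan$beams), beam_to_list),
              normalization = plan$normalization,
              provenance = plan$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  beams <- lapply(obj$beams, function(l) {
    l$aperture$lengths <- unlist(l$aperture$lengths)
    l$aperture$dim <- unlist(l$aperture$dim)
    l$aperture$pixel_spacing <- unlist(l$aperture$pixel_spacing)
    beam_from_list(l)
  })
  rt_plan(obj$technique, as.numeric(obj$rx), beams, obj$normalization,
          obj$provenance)
}

#' Write a DVH set as CSV
#'
#' Long format: structure, bin edge (Gy), fraction, cc.
#'
#' @param dvhs list of `dvh_curve`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(dvhs, path) {
  rows <- lapply(dvhs, function(d)
    data.frame(structure = d$structure, bin_edge_gy = d$bin_edges,
               fraction = d$fraction, cc = d$cc))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
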