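#' Binary voxel grid
#'
#' Container for a 3D binary occupancy mask with an isotropic voxel size.
#' All voxel-space operations in the package consume this type. Any nonzero
#' value in `occupancy` counts as foreground; no thresholding is performed
#' (segmentation is assumed to have happened upstream).
#'
#' Voxel indices are 1-based; the physical position of voxel `(i, j, k)` is
#' its centre, `(c(i, j, k) - 0.5) * voxel_size_mm`.
#'
#' @param occupancy 3D array (logical or numeric); nonzero means foreground.
#' @param voxel_size_mm isotropic voxel edge length in mm (positive scalar).
#' @param label free-text system name, e.g. `"BD"` or `"PV"`.
#' @return An object of class `voxel_grid` with fields `occupancy` (logical
#'   array), `voxel_size_mm`, and `label`.
#' @examples
#' g <- voxel_grid(array(c(0, 1), c(2, 2, 2)), voxel_size_mm = 0.012)
#' system_volume(g)
#' @export
voxel_grid <- function(occupancy, voxel_size_mm, label = "") {
  if (!is.array(occupancy) || length(dim(occupancy)) != 3)
    stop("occupancy must be a 3D array")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1 ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("voxel_size_mm must be a positive scalar")
  if (any(dim(occupancy) < 1)) stop("all dimensions must be >= 1")
  occ <- occupancy != 0
  if (anyNA(occ)) stop("occupancy contains NA")
  structure(
    list(occupancy = occ, voxel_size_mm = as.numeric(voxel_size_mm),
         label = as.character(label)),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("<voxel_grid%s> %d x %d x %d voxels @ %g mm, %d foreground\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              d[1], d[2], d[3], x$voxel_size_mm, sum(x$occupancy)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$occupancy)

volume_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.(tif|tiff)$", lower)) return("tiff")
  if (grepl("\\.nrrd$", lower)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  stop("unrecognised volume format for '", path,
       "' (expected .tif/.tiff, .nrrd, or .nii/.nii.gz)")
}

check_isotropic <- function(spacing, path) {
  spacing <- spacing[is.finite(spacing) & spacing > 0]
  if (length(spacing) < 3) return(NULL)
  if (max(spacing) - min(spacing) > 1e-6 * max(spacing))
    stop(sprintf(
      "anisotropic voxels in '%s': spacings %g x %g x %g mm; this pipeline assumes isotropy",
      path, spacing[1], spacing[2], spacing[3]))
  spacing[1]
}

#' Read a 3D binary mask
#'
#' Reads a multipage TIFF stack, NRRD, or NIfTI-1 volume into a
#' [voxel_grid()]. Any nonzero voxel counts as foreground. The voxel size is
#' taken from the file header when present (NRRD `spacings`/`space
#' directions`, NIfTI `pixdim`); a `voxel_size_mm` argument overrides the
#' header with a warning on mismatch. TIFF carries no physical spacing, so
#' the argument is required there. Anisotropic headers are a hard error
#' (naming the three spacings) rather than being silently resampled.
#'
#' @param path file path ending in `.tif`/`.tiff`, `.nrrd`, or
#'   `.nii`/`.nii.gz`.
#' @param voxel_size_mm isotropic voxel size in mm; optional when the header
#'   carries one.
#' @param label system name stored in the grid.
#' @return A [voxel_grid()].
#' @seealso [write_volume()], [validate_mask()]
#' @export
read_volume <- function(path, voxel_size_mm = NULL, label = "") {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  fmt <- volume_format(path)
  header_vs <- NULL
  if (fmt == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3) p <- p[, , 1] # drop extra channels
      p
    })
    d <- dim(pages[[1]])
    occ <- array(FALSE, c(d[1], d[2], length(pages)))
    for (k in seq_along(pages)) occ[, , k] <- pages[[k]] != 0
  } else if (fmt == "nrrd") {
    nr <- read_nrrd_raw(path)
    occ <- nr$data != 0
    header_vs <- check_isotropic(nr$spacing, path)
  } else {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    header_vs <- check_isotropic(pd[seq_len(min(3, length(pd)))], path)
    arr <- as.array(img)
    if (length(dim(arr)) > 3) arr <- array(arr, dim(arr)[1:3])
    occ <- arr != 0
  }
  if (is.null(voxel_size_mm)) {
    if (is.null(header_vs))
      stop("no voxel size in '", path, "' header; pass voxel_size_mm")
    voxel_size_mm <- header_vs
  } else if (!is.null(header_vs) &&
             abs(header_vs - voxel_size_mm) > 1e-6 * voxel_size_mm) {
    warning(sprintf(
      "voxel size argument (%g mm) overrides header value (%g mm) in '%s'",
      voxel_size_mm, header_vs, path))
  }
  voxel_grid(occ, voxel_size_mm, label = label)
}

#' Write a 3D binary mask
#'
#' Writes a [voxel_grid()] to a multipage TIFF stack, NRRD (raw-encoded
#' `uint8` with `spacings`), or NIfTI-1 file, chosen by extension. The file
#' re-reads with [read_volume()] to identical occupancy and voxel size
#' (TIFF aside, which stores no spacing).
#'
#' @param grid a [voxel_grid()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  fmt <- volume_format(path)
  occ <- grid$occupancy
  d <- dim(occ)
  if (fmt == "tiff") {
    pages <- lapply(seq_len(d[3]), function(k)
      matrix(as.numeric(occ[, , k]), d[1], d[2]))
    ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 8L),
                   error = function(e) stop("cannot write '", path, "': ",
                                            conditionMessage(e)))
  } else if (fmt == "nrrd") {
    write_nrrd_raw(occ, grid$voxel_size_mm, path)
  } else {
    img <- RNifti::asNifti(array(as.integer(occ), d))
    RNifti::pixdim(img) <- rep(grid$voxel_size_mm, 3)
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

# --- minimal NRRD support (attached, raw or gzip encoding) -----------------

nrrd_types <- c(
  "uchar" = "integer", "unsigned char" = "integer", "uint8" = "integer",
  "uint8_t" = "integer", "char" = "integer", "signed char" = "integer",
  "int8" = "integer", "int8_t" = "integer",
  "short" = "integer", "short int" = "integer", "int16" = "integer",
  "int16_t" = "integer", "ushort" = "integer", "uint16" = "integer",
  "unsigned short" = "integer", "uint16_t" = "integer",
  "int" = "integer", "int32" = "integer", "int32_t" = "integer",
  "float" = "double", "double" = "double")

nrrd_sizes <- c(
  "uchar" = 1, "unsigned char" = 1, "uint8" = 1, "uint8_t" = 1, "char" = 1,
  "signed char" = 1, "int8" = 1, "int8_t" = 1, "short" = 2, "short int" = 2,
  "int16" = 2, "int16_t" = 2, "ushort" = 2, "uint16" = 2,
  "unsigned short" = 2, "uint16_t" = 2, "int" = 4, "int32" = 4,
  "int32_t" = 4, "float" = 4, "double" = 8)

read_nrrd_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1, warn = FALSE)
  if (!grepl("^NRRD", magic)) stop("'", path, "' is not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("unexpected end of NRRD header in '", path, "'")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  ndim <- as.integer(fields[["dimension"]] %||% "0")
  if (ndim != 3) stop("NRRD '", path, "' has dimension ", ndim, "; expected 3")
  sizes <- as.integer(strsplit(fields[["sizes"]], "[[:space:]]+")[[1]])
  type <- fields[["type"]] %||% "uchar"
  if (!type %in% names(nrrd_types)) stop("unsupported NRRD type '", type, "'")
  enc <- tolower(fields[["encoding"]] %||% "raw")
  endian <- tolower(fields[["endian"]] %||% "little")
  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "[[:space:]]+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    spacing <- vapply(vecs, function(v) {
      nums <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
      sqrt(sum(nums^2))
    }, numeric(1))
  }
  n <- prod(sizes)
  if (enc == "raw") {
    vals <- readBin(con, nrrd_types[[type]], n = n, size = nrrd_sizes[[type]],
                    endian = endian,
                    signed = !(type %in% c("uchar", "unsigned char", "uint8",
                                           "uint8_t", "ushort", "uint16",
                                           "unsigned short", "uint16_t")) ||
                             nrrd_sizes[[type]] > 2)
  } else if (enc %in% c("gzip", "gz")) {
    raw_rest <- readBin(con, "raw", n = file.info(path)$size)
    vals <- readBin(memDecompress(raw_rest, type = "gzip"),
                    nrrd_types[[type]], n = n, size = nrrd_sizes[[type]],
                    endian = endian)
  } else stop("unsupported NRRD encoding '", enc, "'")
  if (length(vals) < n) stop("truncated NRRD data in '", path, "'")
  list(data = array(vals, sizes), spacing = spacing)
}

write_nrrd_raw <- function(occ, voxel_size_mm, path) {
  d <- dim(occ)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write '", path, "'"))
  on.exit(close(con))
  header <- c(
    "NRRD0004",
    "# generated by ductr",
    "type: uint8",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %.10g %.10g %.10g",
            voxel_size_mm, voxel_size_mm, voxel_size_mm),
    "encoding: raw",
    "endian: little",
    "")
  writeLines(header, con, sep = "\n")
  writeBin(as.integer(occ), con, size = 1)
  invisible(path)
}

#' Census and quality report for a binary mask
#'
#' Reports the 26-connectivity connected-component census of a mask and
#' flags (without deleting) terminal twigs whose maximal cross-section
#' perpendicular to the local skeleton direction falls below
#' `min_cross_section_voxels`. The default of four voxels mirrors the
#' segmentation inclusion cut-off for the smallest distal canal. Optionally,
#' whole connected components smaller than `prune_below` voxels are removed
#' and the pruned grid returned in the report.
#'
#' @param grid a [voxel_grid()].
#' @param min_cross_section_voxels flag terminal branches whose largest
#'   perpendicular cross-section has fewer foreground voxels than this.
#' @param prune_below if not `NULL`, remove connected components with fewer
#'   voxels than this and include `$pruned_grid` in the report.
#' @return A `mask_report` list: `n_foreground_voxels`,
#'   `n_components_26conn`, `smallest_component_voxels`, `is_binary`,
#'   `flagged_twigs` (data frame of sub-threshold terminal links), and
#'   optionally `pruned_grid`.
#' @export
validate_mask <- function(grid, min_cross_section_voxels = 4,
                          prune_below = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  occ <- grid$occupancy
  d <- dim(occ)
  nfg <- sum(occ)
  if (nfg == 0) {
    rep <- list(n_foreground_voxels = 0L, n_components_26conn = 0L,
                smallest_component_voxels = NA_integer_, is_binary = TRUE,
                flagged_twigs = empty_twig_table())
    class(rep) <- "mask_report"
    return(rep)
  }
  lab <- cpp_label26(occ, d)
  sizes <- tabulate(lab[lab > 0])
  flagged <- flag_thin_twigs(grid, min_cross_section_voxels)
  rep <- list(
    n_foreground_voxels = as.integer(nfg),
    n_components_26conn = length(sizes),
    smallest_component_voxels = as.integer(min(sizes)),
    is_binary = TRUE,
    flagged_twigs = flagged)
  if (!is.null(prune_below)) {
    keep <- which(sizes >= prune_below)
    occ2 <- array(lab %in% keep & occ, d)
    rep$pruned_grid <- voxel_grid(occ2, grid$voxel_size_mm, grid$label)
    rep$n_pruned_components <- length(sizes) - length(keep)
  }
  class(rep) <- "mask_report"
  rep
}

#' @export
print.mask_report <- function(x, ...) {
  cat(sprintf("<mask_report> %d foreground voxels, %d component(s) (smallest %s)\n",
              x$n_foreground_voxels, x$n_components_26conn,
              x$smallest_component_voxels))
  if (nrow(x$flagged_twigs))
    cat(sprintf("  %d terminal twig(s) below cross-section threshold\n",
                nrow(x$flagged_twigs)))
  invisible(x)
}

empty_twig_table <- function() {
  data.frame(link_id = integer(), x_mm = numeric(), y_mm = numeric(),
             z_mm = numeric(), max_cross_section_voxels = integer())
}

# Flag terminal links whose maximal perpendicular cross-section is below the
# threshold. The cross-section at a chain point is the count of foreground
# voxels 26-connected to the point within a slab one voxel thick
# perpendicular to the local chain direction.
flag_thin_twigs <- function(grid, min_cross_section_voxels) {
  skel <- tryCatch(skeletonize_mask(grid), error = function(e) NULL)
  if (is.null(skel)) return(empty_twig_table())
  g <- graph_from_skeleton(skel)
  out <- empty_twig_table()
  endpoints <- g$nodes$id[g$nodes$kind == "endpoint"]
  vs <- grid$voxel_size_mm
  # Probe cross-sections at 2, 4, ..., 10 voxels in from the endpoint. The
  # terminal twig is the leading run of sub-threshold cross-sections; its
  # maximal cross-section is reported. Returns NA when the distal samples
  # are not thin (no twig).
  twig_cross_section <- function(chain) {
    n <- nrow(chain)
    s <- arc_positions(chain)
    at <- s[n] - vs * c(2, 4, 6, 8, 10)
    at <- at[at > 0]
    if (!length(at)) at <- s[n] / 2
    probes <- vapply(at, function(a) which.min(abs(s - a)), integer(1))
    probes <- pmax(2L, pmin(n - 1L, probes))
    cs <- vapply(probes, function(i) {
      lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
      dirv <- chain[hi, ] - chain[lo, ]
      nv <- sqrt(sum(dirv^2))
      if (nv == 0) return(NA_integer_)
      cross_section_count(grid, chain[i, ], dirv / nv)
    }, integer(1))
    cs <- cs[!is.na(cs)]
    if (!length(cs)) return(NA_integer_)
    run <- cumprod(cs < min_cross_section_voxels) == 1
    if (!run[1] || (length(cs) >= 2 && !run[2])) return(NA_integer_)
    max(cs[run])
  }
  for (li in seq_len(nrow(g$links))) {
    lk <- g$links[li, ]
    chain <- g$chains[[li]]
    if (nrow(chain) < 3) next
    for (end in c("node_a", "node_b")) {
      ep <- lk[[end]]
      if (!(ep %in% endpoints)) next
      ch <- if (end == "node_a") chain[rev(seq_len(nrow(chain))), ] else chain
      cs <- twig_cross_section(ch)
      if (!is.na(cs)) {
        pos <- unlist(g$nodes[g$nodes$id == ep, c("x_mm", "y_mm", "z_mm")])
        out <- rbind(out, data.frame(
          link_id = lk$id, x_mm = pos[1], y_mm = pos[2], z_mm = pos[3],
          max_cross_section_voxels = as.integer(cs)))
      }
    }
  }
  rownames(out) <- NULL
  out
}

# Count foreground voxels in the one-voxel-thick slab through `point_mm`
# perpendicular to unit vector `dirv`, restricted to those 26-connected to
# the seed voxel within the slab (so parallel neighbouring branches are not
# counted). Search radius 15 voxels.
cross_section_count <- function(grid, point_mm, dirv, max_radius_vox = 15) {
  occ <- grid$occupancy
  d <- dim(occ)
  vs <- grid$voxel_size_mm
  seed <- pmin(pmax(mm_to_voxindex(matrix(point_mm, 1), vs), 1L),
               matrix(d, 1))
  in_slab <- function(idx) {
    rel <- sweep(vox_centers_mm(idx, vs), 2, point_mm)
    abs(rel %*% dirv) <= 0.5 * vs + 1e-9 &
      sqrt(rowSums(rel^2)) <= max_radius_vox * vs
  }
  if (!occ[seed] || !in_slab(seed)) return(0L)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  seen <- new.env(hash = TRUE)
  key <- function(v) paste(v, collapse = ",")
  assign(key(seed), TRUE, envir = seen)
  queue <- list(as.integer(seed))
  count <- 0L
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    count <- count + 1L
    nb <- sweep(offsets, 2, cur, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, ]
      k <- key(v)
      if (!is.null(seen[[k]])) next
      if (!occ[v[1], v[2], v[3]]) next
      if (!in_slab(matrix(v, 1))) next
      assign(k, TRUE, envir = seen)
      queue[[length(queue) + 1]] <- as.integer(v)
    }
  }
  count
}
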