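#' Persist / load a phantom as a directory of standard files
#'
#' Writes NIfTI masks and signal, TCK truth streamlines (with metadata
#' sidecar), FSL-style bval/bvec files, the stick table as TSV and the
#' spec as JSON (seed included), so every downstream stage can be re-run
#' from disk.
#'
#' @param phantom a `csv_phantom`
#' @param dir output directory (created if needed)
#' @return `write_phantom()`: `dir` invisibly; `read_phantom()`: a
#'   `csv_phantom` equivalent to the written one.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_volume(phantom$signal, p("signal.nii.gz"))
  write_volume(phantom$wm_mask, p("wm_mask.nii.gz"))
  for (h in names(phantom$csv_masks))
    write_volume(phantom$csv_masks[[h]], p(paste0("csv_", h, ".nii.gz")))
  dir.create(p("rois"), showWarnings = FALSE)
  for (rn in names(phantom$waypoint_rois))
    write_volume(phantom$waypoint_rois[[rn]], p("rois", paste0(rn, ".nii.gz")))
  write_streamlines(phantom$truth_streamlines, p("truth.tck"))
  write_gradient_table(phantom$gtab, p("bvals.txt"), p("bvecs.txt"))
  utils::write.table(phantom$orientation_field$sticks, p("sticks.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  spec <- phantom$spec
  spec_json <- list(
    grid_shape = spec$grid_shape, voxel_size = spec$voxel_size,
    csv_centres = spec$csv_centres, snr = spec$snr, seed = spec$seed,
    csv_size = spec$csv_size, f_iso_wm = spec$f_iso_wm, d_ax = spec$d_ax,
    d_iso = spec$d_iso, S0 = spec$S0, noise_model = spec$noise_model,
    csv_capture_mm = spec$csv_capture_mm, csv_target = spec$csv_target,
    roi_owner = as.list(phantom$roi_owner),
    bundles = lapply(spec$bundles, function(b)
      list(name = b$name, centreline = b$centreline, radius = b$radius,
           n_streamlines = b$n_streamlines, roi_stations = b$roi_stations,
           csv_fraction = b$csv_fraction, exit_fraction = b$exit_fraction)))
  jsonlite::write_json(spec_json, p("spec.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  p <- function(...) file.path(dir, ...)
  sj <- jsonlite::read_json(p("spec.json"), simplifyVector = TRUE)
  bundles <- lapply(seq_len(nrow_of(sj$bundles)), function(q) {
    b <- bundle_row(sj$bundles, q)
    bundle_spec(b$name, matrix(unlist(b$centreline), ncol = 3),
                radius = b$radius, n_streamlines = b$n_streamlines,
                roi_stations = unlist(b$roi_stations),
                csv_fraction = b$csv_fraction,
                exit_fraction = b$exit_fraction)
  })
  spec <- phantom_spec(
    grid_shape = sj$grid_shape, voxel_size = sj$voxel_size, bundles = bundles,
    csv_centres = lapply(sj$csv_centres, unlist),
    snr = if (is.character(sj$snr)) Inf else sj$snr, seed = sj$seed,
    csv_size = sj$csv_size, f_iso_wm = sj$f_iso_wm, d_ax = sj$d_ax,
    d_iso = sj$d_iso, S0 = sj$S0, noise_model = sj$noise_model,
    csv_capture_mm = sj$csv_capture_mm, csv_target = sj$csv_target)
  grid <- phantom_grid(spec)
  wm_vol <- read_volume(p("wm_mask.nii.gz"))
  wm_mask <- binary_mask(wm_vol$data > 0, wm_vol$affine, name = "wm",
                         allow_empty = TRUE)
  wm_mask$hemisphere <- "midline"
  csv_masks <- lapply(stats::setNames(nm = names(spec$csv_centres)), function(h) {
    v <- read_volume(p(paste0("csv_", h, ".nii.gz")))
    binary_mask(v$data > 0, v$affine, name = paste0("CSv_", h), hemisphere = h)
  })
  roi_owner <- unlist(sj$roi_owner)
  rois <- lapply(stats::setNames(nm = names(roi_owner)), function(rn) {
    v <- read_volume(p("rois", paste0(rn, ".nii.gz")))
    binary_mask(v$data > 0, v$affine, name = rn)
  })
  sticks <- tibble::as_tibble(utils::read.delim(p("sticks.tsv")))
  stick_mask <- array(FALSE, dim = spec$grid_shape)
  if (nrow(sticks) > 0)
    stick_mask[cbind(sticks$i, sticks$j, sticks$k) + 1] <- TRUE
  f_iso <- array(1, dim = spec$grid_shape)
  f_iso[stick_mask] <- spec$f_iso_wm
  structure(list(
    spec = spec, grid = grid,
    truth_streamlines = read_streamlines(p("truth.tck")),
    csv_masks = csv_masks, waypoint_rois = rois, roi_owner = roi_owner,
    tract_definitions = phantom_tract_definitions(spec, roi_owner),
    orientation_field = list(sticks = sticks, f_iso = f_iso,
                             stick_mask = stick_mask),
    wm_mask = wm_mask, gtab = read_gradient_table(p("bvals.txt"), p("bvecs.txt")),
    signal = read_volume(p("signal.nii.gz"))), class = "csv_phantom")
}

nrow_of <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
bundle_row <- function(x, q) if (is.data.frame(x)) lapply(x, `[[`, q) else x[[q]]
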