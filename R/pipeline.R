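#' Run the full SAT/VAT segmentation pipeline on a volume
#'
#' End-to-end automated fat quantification: body detection, TAT
#' thresholding, non-fat segmentation, per-slice convex-hull closed paths
#' with contact correction, separation-mask split into SAT/VAT, bone
#' detection by 3-D region growing, and marrow-fat removal with the bone
#' correction mask.  The pipeline is fully deterministic.
#'
#' @param volume a [ct_volume].
#' @param thresholds a [thresholds] object.
#' @param opening_radius_mm disc radius for skin removal, mm.
#' @param slice_range optional `c(first, last)` restriction to the abdominal
#'   slice range (e.g. diaphragm to coccyx, excluding the pelvic cavity).
#' @param min_area minimum body-component area, pixels (see
#'   [detect_body_region()]).
#' @return An object of class `fat_quant` with elements `seg` (corrected
#'   [fat_segmentation]), `seg_uncorrected`, `body`, `nonfat`, `separation`,
#'   `bones`, `correction`, `areas`, `volumes` (a `volume_report`),
#'   `spacing`, and the parameters used (`config`).
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(3, 96, 96),
#'                                     spacing = c(3, 3, 5)))
#' res <- segment_fat(ph$volume)
#' res$volumes
#' @export
segment_fat <- function(volume, thresholds = ctadipose::thresholds(),
                        opening_radius_mm = 3, slice_range = NULL,
                        min_area = 100) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  if (!is.null(slice_range)) {
    slice_range <- as.integer(slice_range)
    if (length(slice_range) != 2L || slice_range[1] > slice_range[2] ||
        slice_range[1] < 1L || slice_range[2] > d[1])
      stop("invalid slice range (", paste(slice_range, collapse = ":"),
           ") for a volume of ", d[1], " slices")
    volume <- ct_volume(volume$voxels[slice_range[1]:slice_range[2], , ,
                                      drop = FALSE],
                        volume$spacing, volume$meta)
    d <- dim(volume$voxels)
  }
  body <- detect_body_region(volume, thresholds, min_area = min_area)
  tat <- detect_tat(volume, body, thresholds)
  nonfat <- segment_nonfat(body, tat, opening_radius_mm, volume$spacing)
  paths <- vector("list", d[1])
  for (s in seq_len(d[1])) {
    sl <- matrix(nonfat[s, , ], d[2], d[3])
    hull <- convex_hull_path(sl, slice_index = s)
    if (is.null(hull)) next
    paths[[s]] <- correct_closed_path(hull, sl)
  }
  sep <- build_separation_mask(paths, d)
  seg0 <- split_sat_vat(tat, sep)
  bones <- detect_bones(volume, body, thresholds)
  corr <- build_correction_mask(bones, nonfat, body)
  areas <- vapply(corr$components, classify_slice_area, character(1))
  seg <- apply_vat_correction(seg0, corr, areas)
  structure(list(
    seg = seg, seg_uncorrected = seg0, body = body, nonfat = nonfat,
    separation = sep, bones = bones, correction = corr, areas = areas,
    volumes = compute_volumes(seg, volume$spacing),
    spacing = volume$spacing,
    config = list(thresholds = unclass(thresholds),
                  opening_radius_mm = opening_radius_mm,
                  slice_range = slice_range, min_area = min_area)
  ), class = "fat_quant")
}

#' @export
print.fat_quant <- function(x, ...) {
  cat("<fat_quant> automated SAT/VAT quantification\n")
  print(x$volumes)
  cat(sprintf("  slice classes: %s\n",
              paste(sprintf("%s:%d", names(table(x$areas)), table(x$areas)),
                    collapse = " ")))
  invisible(x)
}

#' Encode a fat segmentation as a label volume
#'
#' Label codes: 0 = background, 1 = SAT, 2 = VAT, 3 = removed bone fat.
#'
#' @param seg a [fat_segmentation].
#' @return Integer 3-D array of label codes.
#' @export
seg_to_labels <- function(seg) {
  stopifnot(inherits(seg, "fat_segmentation"))
  lab <- array(0L, dim = dim(seg$tat))
  lab[seg$sat] <- 1L
  lab[seg$vat] <- 2L
  lab[seg$removed_bone_fat] <- 3L
  lab
}

#' Decode a label volume into compartment masks
#'
#' @param labels integer array with codes 0..3 (see [seg_to_labels()]).
#' @return List of logical masks `tat`, `sat`, `vat`, `removed_bone_fat`.
#' @export
labels_to_masks <- function(labels) {
  list(tat = array(labels %in% 1:3, dim(labels)),
       sat = labels == 1L, vat = labels == 2L,
       removed_bone_fat = labels == 3L)
}

# per-slice + total volume table
.report_table <- function(seg, spacing) {
  vx <- voxel_volume_ml(spacing)
  d <- dim(seg$tat)
  per <- data.frame(
    slice = seq_len(d[1]),
    sat_voxels = apply(seg$sat, 1, sum),
    vat_voxels = apply(seg$vat, 1, sum),
    removed_bone_fat_voxels = apply(seg$removed_bone_fat, 1, sum)
  )
  per$sat_ml <- per$sat_voxels * vx
  per$vat_ml <- per$vat_voxels * vx
  per$tat_ml <- per$sat_ml + per$vat_ml
  per
}

.provenance <- function(config, extra = list()) {
  c(list(package = "ctadipose",
         version = as.character(utils::packageVersion("ctadipose")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    config, extra)
}

#' Segment a volume from disk and write all artifacts
#'
#' Reads a CT volume (DICOM directory, NIfTI or MetaImage file), runs
#' [segment_fat()], and writes: a SAT/VAT/TAT label volume
#' (`labels.nii`), per-slice and total volume reports (`report.csv`,
#' `report.json`), and a provenance record (`provenance.json`) holding every
#' threshold and decision parameter.  Outputs are byte-reproducible for
#' identical inputs and configuration.
#'
#' @param input_path DICOM series directory or volume file.
#' @param out_dir output directory, created if needed.
#' @param thresholds,opening_radius_mm,slice_range,min_area passed to
#'   [segment_fat()].
#' @return Invisibly, a list with `status = 0L`, the `result` object and the
#'   output `paths`.
#' @export
run_segment <- function(input_path, out_dir,
                        thresholds = ctadipose::thresholds(),
                        opening_radius_mm = 3, slice_range = NULL,
                        min_area = 100) {
  volume <- if (dir.exists(input_path)) read_ct_series(input_path)
            else read_volume(input_path)
  res <- segment_fat(volume, thresholds, opening_radius_mm, slice_range,
                     min_area)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(labels = file.path(out_dir, "labels.nii"),
                csv = file.path(out_dir, "report.csv"),
                json = file.path(out_dir, "report.json"),
                provenance = file.path(out_dir, "provenance.json"))
  write_labels(seg_to_labels(res$seg), res$spacing, paths$labels)
  per <- .report_table(res$seg, res$spacing)
  write.csv(per, paths$csv, row.names = FALSE)
  v <- res$volumes
  jsonlite::write_json(list(
    total = list(tat_ml = v$tat_ml, sat_ml = v$sat_ml, vat_ml = v$vat_ml,
                 voxel_counts = as.list(v$voxel_counts)),
    per_slice = per
  ), paths$json, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(.provenance(res$config,
                                   list(input = basename(input_path),
                                        spacing_mm = res$spacing)),
                       paths$provenance, auto_unbox = TRUE, digits = NA)
  invisible(list(status = 0L, result = res, paths = paths))
}

#' Evaluate a predicted label volume against a reference
#'
#' Computes voxelwise confusion counts and sensitivity/specificity/accuracy/
#' Dice per compartment (TAT, SAT, VAT) between two label volumes on one
#' grid, and writes `metrics.csv` / `metrics.json`.  A compartment absent
#' from both volumes yields undefined (`NA`) metrics and is flagged, not an
#' error.
#'
#' @param pred_path,truth_path label volumes (codes as in [seg_to_labels()];
#'   for the reference, code 3 marks marrow fat counted in TAT only).
#' @param out_dir output directory.
#' @param eval_domain `"body"` restricts evaluation to a body mask read from
#'   `body_path`; `"image"` uses the full grid.
#' @param body_path optional body mask volume (required for
#'   `eval_domain = "body"`).
#' @return Invisibly, `status = 0L`, the metrics table, and output paths.
#' @export
run_evaluate <- function(pred_path, truth_path, out_dir,
                         eval_domain = c("image", "body"), body_path = NULL) {
  eval_domain <- match.arg(eval_domain)
  pred <- read_labels(pred_path)
  truth <- read_labels(truth_path)
  if (!identical(dim(pred), dim(truth)))
    stop("label volumes are on different grids: ",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"))
  domain <- NULL
  if (eval_domain == "body") {
    if (is.null(body_path))
      stop("eval_domain = \"body\" needs `body_path`")
    domain <- read_labels(body_path) > 0
    if (!identical(dim(domain), dim(pred)))
      stop("body mask is on a different grid")
  }
  comp <- list(tat = 1:3, sat = 1L, vat = 2L)
  rows <- lapply(names(comp), function(nm) {
    p <- array(pred %in% comp[[nm]], dim(pred))
    t <- array(truth %in% comp[[nm]], dim(truth))
    if (!any(p) && !any(t))
      return(data.frame(compartment = nm, tp = 0L, fp = 0L, tn = 0L, fn = 0L,
                        sensitivity = NA_real_, specificity = NA_real_,
                        accuracy = NA_real_, dsc = NA_real_,
                        note = "absent from both volumes"))
    cts <- confusion(p, t, domain)
    m <- evaluate_counts(cts)
    data.frame(compartment = nm, tp = cts$tp, fp = cts$fp, tn = cts$tn,
               fn = cts$fn, sensitivity = m$sensitivity,
               specificity = m$specificity, accuracy = m$accuracy,
               dsc = m$dsc, note = "")
  })
  tab <- do.call(rbind, rows)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(csv = file.path(out_dir, "metrics.csv"),
                json = file.path(out_dir, "metrics.json"))
  write.csv(tab, paths$csv, row.names = FALSE)
  jsonlite::write_json(tab, paths$json, auto_unbox = TRUE, digits = NA)
  invisible(list(status = 0L, metrics = tab, paths = paths))
}

#' Generate phantom volumes and ground truth on disk
#'
#' Writes, for each spec, the HU volume (`<name>_volume.nii`), the ground-
#' truth label volume (`<name>_truth.nii`, codes as in [seg_to_labels()]
#' with marrow fat as code 3), the body-truth mask, and a JSON echo of the
#' spec.
#'
#' @param spec_or_suite `"suite"` for [default_suite()], a single
#'   [phantom_spec], a list of specs, or the path of a JSON file holding
#'   `phantom_spec` arguments.
#' @param out_dir output directory.
#' @return Invisibly, `status = 0L` and the per-phantom file paths.
#' @export
run_phantom <- function(spec_or_suite = "suite", out_dir) {
  specs <-
    if (inherits(spec_or_suite, "phantom_spec")) list(phantom = spec_or_suite)
    else if (is.list(spec_or_suite)) spec_or_suite
    else if (identical(spec_or_suite, "suite")) default_suite()
    else {
      args <- jsonlite::fromJSON(spec_or_suite)
      if (!is.list(args) || is.null(names(args)) ||
          !all(names(args) %in% names(formals(phantom_spec))))
        stop("malformed phantom spec file: ", spec_or_suite)
      if (!is.null(args$hu)) args$hu <- unlist(args$hu)
      list(phantom = do.call(phantom_spec, args))
    }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in names(specs)) {
    ph <- generate_phantom(specs[[nm]])
    p <- list(volume = file.path(out_dir, paste0(nm, "_volume.nii")),
              truth = file.path(out_dir, paste0(nm, "_truth.nii")),
              body = file.path(out_dir, paste0(nm, "_body.nii")),
              spec = file.path(out_dir, paste0(nm, "_spec.json")))
    write_volume(ph$volume, p$volume)
    write_labels(seg_to_labels(ph$truth), ph$volume$spacing, p$truth)
    write_mask(ph$body_truth, ph$volume$spacing, p$body)
    sp <- specs[[nm]]
    jsonlite::write_json(unclass(sp)[!vapply(unclass(sp), is.null, TRUE)],
                         p$spec, auto_unbox = TRUE, digits = NA)
    paths[[nm]] <- p
  }
  invisible(list(status = 0L, paths = paths))
}
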