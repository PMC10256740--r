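# Readers and writers for the pipeline's on-disk formats. All physical
# quantities carry explicit units in column names (x_um, tau_s,
# D_um2_per_s). Movies are multi-page TIFF with a JSON sidecar holding the
# calibration (pixel size, frame interval); on conflict the sidecar wins.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a movie stack as multi-page TIFF + JSON sidecar
#'
#' Intensities are stored as 32-bit float TIFF pages scaled to [0, 1]; the
#' scale factor, pixel size (um), frame interval (s) and channel are stored
#' in a `<path>.json` sidecar. Reading without calibration metadata is an
#' error naming the missing field.
#'
#' @param movie a `movie_stack`.
#' @param path TIFF file path.
#' @return `write_movie`: the path, invisibly. `read_movie`: a
#'   `movie_stack`.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  scale <- max(movie$frames, 1e-12)
  pages <- lapply(seq_len(dim(movie$frames)[3]),
                  function(t) movie$frames[, , t] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(pixel_size_um = movie$pixel_size,
                            frame_interval_s = movie$frame_interval,
                            channel = movie$channel, intensity_scale = scale),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  stop_arg(file.exists(path), sprintf("no such file: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e)
                      stop(sprintf("malformed TIFF '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE))
  if (is.matrix(pages)) pages <- list(pages)
  sc <- sidecar_path(path)
  stop_arg(file.exists(sc),
           sprintf("movie '%s' has no calibration sidecar '%s' (need pixel_size_um, frame_interval_s)",
                   path, basename(sc)))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (field in c("pixel_size_um", "frame_interval_s"))
    if (is.null(meta[[field]]))
      stop(sprintf("movie metadata missing field '%s'", field), call. = FALSE)
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]] * scale
  movie_stack(frames, pixel_size = meta$pixel_size_um,
              frame_interval = meta$frame_interval_s,
              channel = if (is.null(meta$channel)) "ch1" else meta$channel)
}

#' Read a binary/label mask from TIFF or PNG
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @return integer matrix (intensities scaled to their integer labels for
#'   label masks; 0 = background).
#' @export
read_mask <- function(path) {
  stop_arg(file.exists(path), sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported mask format '.%s' (use TIFF or PNG)", ext),
         call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * ifelse(max(img) <= 1, 255, 1))
}

# Generic checked table reader: `required` columns must be present; unknown
# extra columns are kept with a warning.
read_table_checked <- function(path, required, sep, what, allow_extra = FALSE) {
  stop_arg(file.exists(path), sprintf("no such file: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s '%s' missing column(s): %s", what, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(df), required)
  if (length(extra) > 0 && !allow_extra)
    warning(sprintf("%s '%s' has extra column(s) kept as-is: %s", what, path,
                    paste(extra, collapse = ", ")))
  df
}

#' Tracks, spots, counts, and annotation file IO
#'
#' CSV for spots (`frame`, `x_um`, `y_um`, `quality`) and tracks
#' (`track_id`, `frame`, `x_um`, `y_um`); TSV for count matrices (gene
#' column + one column per sample), sample metadata (`sample`,
#' `compartment`, `condition`) and CLIP annotations (`gene`,
#' `tags_per_kb`). Write-then-read round trips are lossless; extra columns
#' are preserved with a warning on read.
#'
#' @param tracks a `track_set` (or its `tracks` data.frame).
#' @param path file path.
#' @param frame_interval frame interval to attach on read, s.
#' @return readers return data.frames (or a `track_set`); writers return
#'   the path invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_tracks <- function(tracks, path) {
  tb <- if (inherits(tracks, "track_set")) tracks$tracks else tracks
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_tracks <- function(path, frame_interval = 0.1) {
  df <- read_table_checked(path, c("track_id", "frame", "x_um", "y_um"),
                           ",", "tracks CSV")
  track_set(df, frame_interval = frame_interval)
}

#' @rdname table_io
#' @export
write_spots <- function(spots, path) {
  utils::write.csv(spots, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_spots <- function(path) {
  read_table_checked(path, c("frame", "x_um", "y_um", "quality"), ",",
                     "spots CSV")
}

#' @rdname table_io
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), as.data.frame(counts),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_counts <- function(path) {
  df <- read_table_checked(path, "gene", "\t", "counts TSV",
                           allow_extra = TRUE)  # sample columns vary
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' @rdname table_io
#' @export
read_sample_metadata <- function(path) {
  read_table_checked(path, c("sample", "compartment", "condition"), "\t",
                     "sample metadata TSV")
}

#' @rdname table_io
#' @export
read_clip_annotation <- function(path) {
  read_table_checked(path, c("gene", "tags_per_kb"), "\t",
                     "CLIP annotation TSV")
}

#' Write / read neurite geometry as JSON
#'
#' @param geometry a [neurite_geometry()].
#' @param path JSON path.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "neurite_geometry"))
  jsonlite::write_json(list(cell_id = geometry$cell_id,
                            soma_centroid_um = geometry$soma,
                            neurites_um = lapply(geometry$neurites, unname)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  stop_arg(file.exists(path), sprintf("no such file: %s", path))
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("soma_centroid_um", "neurites_um"))
    if (is.null(js[[field]]))
      stop(sprintf("geometry JSON missing field '%s'", field), call. = FALSE)
  neur <- js$neurites_um
  if (is.array(neur) && length(dim(neur)) == 3)  # equal-size polylines simplify
    neur <- lapply(seq_len(dim(neur)[1]), function(i) neur[i, , ])
  if (is.matrix(neur)) neur <- list(neur)
  neur <- lapply(neur, function(p) matrix(unlist(p), ncol = 2, byrow = !is.matrix(p)))
  neurite_geometry(js$soma_centroid_um, neur,
                   cell_id = if (is.null(js$cell_id)) 1L else js$cell_id)
}

# ---- pipeline configuration and stage runner -------------------------------

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "results",
    simulate = list(kind = "brownian", D = 0.01, v = 1, n_tracks = 10,
                    nx = 128, ny = 128, pixel_size = 0.1,
                    frame_interval = 0.1, n_frames = 100, noise = "none"),
    tracking = list(diameter = 0.5, max_displacement = 0.5, min_frames = 21,
                    rolling_ball_radius = 3),
    dynamics = list(max_lag = 7, convention = "slope4")
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys take documented defaults; unknown keys are rejected.
#'
#' @param path YAML file, or `NULL` for the full default configuration.
#' @return configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, upd, prefix = "") {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown) > 0)
      stop(sprintf("unknown configuration key(s): %s",
                   paste0(prefix, unknown, collapse = ", ")), call. = FALSE)
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]]))
        merge_cfg(base[[k]], upd[[k]], paste0(prefix, k, "."))
      else upd[[k]]
    }
    base
  }
  merge_cfg(cfg, user)
}

#' Run a pipeline stage
#'
#' Stages: `"simulate"` (tracks + rendered movie), `"track"` (detect, link,
#' filter on the simulated movie), `"dynamics"` (per-track/per-cell summary
#' of the filtered tracks). Each stage writes its artifacts under
#' `config$out_dir` together with a `manifest_<stage>.json` listing
#' parameters, seed, inputs, outputs and md5 checksums, so a run is
#' reproducible from the manifest and configuration alone.
#'
#' @param config configuration list from [read_config()].
#' @param stage stage name.
#' @return list of output paths, invisibly.
#' @export
run_pipeline <- function(config, stage) {
  stages <- c("simulate", "track", "dynamics")
  if (!stage %in% stages)
    stop(sprintf("unknown stage '%s'; valid stages: %s", stage,
                 paste(stages, collapse = ", ")), call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (stage == "simulate") {
    sc <- config$simulate
    acq <- acquisition_spec(nx = sc$nx, ny = sc$ny, pixel_size = sc$pixel_size,
                            frame_interval = sc$frame_interval,
                            n_frames = sc$n_frames, noise = sc$noise,
                            seed = derive_seed(config$seed, "simulate"))
    model <- switch(sc$kind,
      brownian = motion_model("brownian", D = sc$D),
      directed = motion_model("directed", v = sc$v),
      stationary = motion_model("stationary"),
      stop(sprintf("unsupported simulate.kind '%s'", sc$kind), call. = FALSE))
    ts <- simulate_tracks(model, acq, sc$n_tracks)
    mv <- render_movie(ts, acq)
    paths$tracks <- file.path(out_dir, "ground_truth_tracks.csv")
    paths$movie <- file.path(out_dir, "movie.tif")
    write_tracks(ts, paths$tracks)
    write_movie(mv, paths$movie)
  } else if (stage == "track") {
    tc <- config$tracking
    movie_path <- file.path(out_dir, "movie.tif")
    stop_arg(file.exists(movie_path),
             "upstream artifact missing: movie.tif (run the simulate stage first)")
    mv <- read_movie(movie_path)
    spots <- detect_spots(mv, diameter = tc$diameter,
                          rolling_ball_radius = tc$rolling_ball_radius)
    ts <- filter_tracks(link_spots(spots, tc$max_displacement,
                                   mv$frame_interval),
                        min_frames = tc$min_frames)
    paths$spots <- file.path(out_dir, "spots.csv")
    paths$tracks <- file.path(out_dir, "tracks.csv")
    write_spots(spots, paths$spots)
    write_tracks(ts, paths$tracks)
  } else {
    dc <- config$dynamics
    tracks_path <- file.path(out_dir, "tracks.csv")
    stop_arg(file.exists(tracks_path),
             "upstream artifact missing: tracks.csv (run the track stage first)")
    ts <- read_tracks(tracks_path,
                      frame_interval = config$simulate$frame_interval)
    dyn <- summarize_dynamics(ts, max_lag = dc$max_lag,
                              convention = dc$convention)
    paths$per_track <- file.path(out_dir, "dynamics_per_track.tsv")
    paths$ensemble <- file.path(out_dir, "dynamics_ensemble.tsv")
    utils::write.table(dyn$per_track, paths$per_track, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(dyn$ensemble, paths$ensemble, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  manifest <- list(stage = stage, seed = config$seed,
                   parameters = config[[switch(stage, simulate = "simulate",
                                               track = "tracking",
                                               dynamics = "dynamics")]],
                   package_version = as.character(utils::packageVersion("rnptrack")),
                   outputs = lapply(paths, function(p)
                     list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir,
                                           sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
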