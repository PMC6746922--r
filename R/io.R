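#' Read an electrode LAT table
#'
#' The interchange dialect is a CSV with columns `id, x, y, z, lat` and
#' one row per (electrode, LAT); clinical exports can be converted to it
#' externally. Rows with an empty `lat` mark no-signal (scar) electrodes:
#' the electrode is kept with zero LATs and a warning counts them.
#'
#' @param path CSV file. If a `<path>.json` sidecar exists, its
#'   `cycle_length`/`truth` entries are attached.
#' @return list with `set` (an `electrode_set`), `lat_map`,
#'   `cycle_length` and `truth`.
#' @export
read_lat_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "z", "lat")
  if (!all(need %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric %s coordinate in row %d", col, bad[1]))
    df[[col]] <- v
  }
  lat <- suppressWarnings(as.numeric(df$lat))
  has_lat <- !is.na(lat)
  dup <- duplicated(data.frame(df$id, lat)[has_lat, ])
  if (any(dup))
    stop("duplicate (id, lat) rows in ", path)
  ids <- unique(df$id)
  pos <- do.call(rbind, lapply(ids, function(i) {
    r <- df[df$id == i, , drop = FALSE][1, ]
    c(r$x, r$y, r$z)
  }))
  lat_map <- lapply(ids, function(i) sort(lat[df$id == i & has_lat]))
  names(lat_map) <- as.character(ids)
  n_empty <- sum(lengths(lat_map) == 0)
  if (n_empty)
    warning(sprintf("%d electrode(s) carry no LAT (scar/no-signal)",
                    n_empty))
  cl <- NA_real_; truth <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$cycle_length)) cl <- as.numeric(meta$cycle_length)
    if (!is.null(meta$truth)) {
      truth <- meta$truth
      if (!is.null(truth$core)) truth$core <- matrix(unlist(truth$core),
                                                     ncol = 3, byrow = FALSE)
    }
  }
  list(set = electrode_set(ids, pos), lat_map = lat_map,
       cycle_length = cl, truth = truth)
}

#' Write an activation field as a LAT table
#'
#' @param field an `activation_field`.
#' @param path CSV path; truth and cycle length go to a `<path>.json`
#'   sidecar.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @export
write_lat_table <- function(field, path, sidecar = TRUE) {
  rows <- do.call(rbind, lapply(seq_along(field$ids), function(i) {
    v <- field$lats[[i]]
    if (!length(v)) v <- NA_real_
    data.frame(id = rep(field$ids[i], length(v)),
               x = field$positions[i, 1], y = field$positions[i, 2],
               z = field$positions[i, 3], lat = v, row.names = NULL)
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  if (sidecar) {
    meta <- list(cycle_length = field$cycle_length)
    if (!is.null(field$truth))
      meta$truth <- list(kind = field$truth$kind,
                         core = apply(field$truth$core, 1, as.numeric,
                                      simplify = FALSE))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Serialize a diagnosis to JSON
#'
#' The report embeds the full parameter set (CV bounds, delta_t,
#' thresholds, seed-free provenance), so re-running with identical input
#' and configuration reproduces it byte for byte.
#'
#' @param x a `dgmap` object.
#' @param path output JSON path.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "dgmap"))
  rep <- list(
    mechanism = x$mechanism,
    cores = lapply(x$cores, function(co) list(
      center_mm = as.numeric(co$center),
      center_median_mm = as.numeric(co$center_median),
      n_cycles = co$n_cycles,
      member_electrodes = co$member_electrodes,
      representative_cycle = co$representative$ids)),
    focal_sources = lapply(x$focal_sources, function(s) list(
      origin_mm = as.numeric(s$origin),
      electrodes = s$electrodes,
      earliest_electrode = s$earliest_electrode,
      earliest_lat = s$earliest_lat)),
    regions = if (!is.null(x$regions))
      list(core_label = stats::setNames(as.list(x$regions$core),
                                        x$regions$id)),
    provenance = x$config)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
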