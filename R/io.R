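# Delimited-text dialects.  All files are UTF-8 CSV with "." decimal marks;
# metadata travels in leading "# key: value" comment lines so that every
# table stays self-describing (units, coordinate convention, labels).

meta_header <- function(meta) {
  vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]), "")
}

parse_meta <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

read_delim_checked <- function(path, columns) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- parse_meta(lines)
  body_at <- which(!grepl("^#", lines))
  if (!length(body_at)) stopf("%s: no data", path)
  hdr_line <- body_at[1]
  header <- strsplit(lines[hdr_line], ",", fixed = TRUE)[[1]]
  if (!identical(header, columns))
    stopf("%s: expected columns %s, found %s", path,
          paste(columns, collapse = ","), paste(header, collapse = ","))
  data_lines <- body_at[-1]
  if (!length(data_lines)) stopf("%s: no data rows", path)
  fields <- strsplit(lines[data_lines], ",", fixed = TRUE)
  bad <- which(lengths(fields) != length(columns))
  if (length(bad))
    stopf("%s: wrong field count on line(s) %s", path,
          paste(utils::head(data_lines[bad], 5), collapse = ", "))
  mat <- do.call(rbind, fields)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- columns
  num_cols <- setdiff(columns, c("subject", "condition"))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v))
      stopf("%s: non-numeric '%s' on line(s) %s", path, cn,
            paste(utils::head(data_lines[is.na(v)], 5), collapse = ", "))
    df[[cn]] <- v
  }
  attr(df, "meta") <- meta
  df
}

write_delim_meta <- function(df, path, meta = list()) {
  lines <- c(meta_header(meta),
             paste(names(df), collapse = ","),
             do.call(paste, c(lapply(df, function(col)
               if (is.numeric(col)) fmt_num(col) else as.character(col)),
               sep = ",")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

track_columns <- c("frame_index", "time_s", "point_id", "x", "y")

#' Write tracked-point series to per-leaf delimited files
#'
#' One file per leaf, flat dialect with columns
#' `frame_index, time_s, point_id, x, y` (three rows per frame, point ids
#' 1..3) and metadata comment lines for units, coordinate convention and
#' labels.  `convention = "y-down"` exports image-frame coordinates
#' (y axis pointing down).
#'
#' @param tracks named list of [track_series()] (as from
#'   [simulate_tracks()]`$tracks`).
#' @param dir output directory (created if needed).
#' @param convention `"y-up"` (mathematical) or `"y-down"` (image frame).
#' @return invisibly, the written file paths.
#' @export
write_tracks <- function(tracks, dir, convention = c("y-up", "y-down")) {
  convention <- match.arg(convention)
  if (inherits(tracks, "track_series")) tracks <- list(track = tracks)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (id in names(tracks)) {
    tr <- tracks[[id]]
    ys <- cbind(tr$y1, tr$y2, tr$y3)
    if (convention == "y-down") ys <- -ys
    nf <- nrow(tr)
    long <- data.frame(
      frame_index = rep(seq_len(nf) - 1L, each = 3L),
      time_s = rep(tr$time_s, each = 3L),
      point_id = rep(1:3, nf),
      x = as.vector(t(cbind(tr$x1, tr$x2, tr$x3))),
      y = as.vector(t(ys)))
    p <- file.path(dir, paste0(id, ".csv"))
    write_delim_meta(long, p, meta = list(
      units = attr(tr, "units") %||% "mm",
      convention = convention,
      leaf_id = attr(tr, "leaf_id") %||% id,
      condition = attr(tr, "condition") %||% NA))
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read tracked-point series
#'
#' Reads files written in the dialect of [write_tracks()].  Malformed rows
#' (wrong field count, non-numeric coordinates, duplicated frame/point keys)
#' are rejected with their line numbers.
#'
#' @param path a directory (all `*.csv` inside) or explicit file paths.
#' @return named list of [track_series()].
#' @export
read_tracks <- function(path) {
  files <- if (length(path) == 1 && dir.exists(path))
    list.files(path, pattern = "\\.csv$", full.names = TRUE) else path
  if (!length(files) || !all(file.exists(files)))
    stopf("no track files found under %s", paste(path, collapse = ", "))
  out <- list()
  for (f in files) {
    df <- read_delim_checked(f, track_columns)
    meta <- attr(df, "meta")
    key <- paste(df$frame_index, df$point_id)
    if (anyDuplicated(key))
      stopf("%s: duplicated (frame_index, point_id) key: %s", f,
            key[duplicated(key)][1])
    if (!all(df$point_id %in% 1:3))
      stopf("%s: point_id must be 1, 2 or 3", f)
    df <- df[order(df$frame_index, df$point_id), ]
    frames <- unique(df$frame_index)
    if (nrow(df) != 3 * length(frames))
      stopf("%s: every frame needs exactly the three points 1..3", f)
    gp <- function(pid) as.matrix(df[df$point_id == pid, c("x", "y")])
    tr <- track_series(df$time_s[df$point_id == 1], gp(1), gp(2), gp(3),
                       units = meta$units %||% "mm",
                       convention = meta$convention %||% "y-up",
                       leaf_id = meta$leaf_id %||% NA_character_,
                       condition = meta$condition %||% NA_character_)
    out[[sub("\\.csv$", "", basename(f))]] <- tr
  }
  out
}

#' Write / read tensile records
#'
#' Record dialect: columns `time_s, force_N, displacement_m` with the
#' original length in a `# L0_m:` header; geometry sidecar: columns
#' `station, a_m, b_m` (ellipse half-axes in m).
#'
#' @param record data frame `time_s`, `force_N`, `displacement_m` with an
#'   `L0_m` attribute (as from [simulate_tensile()]).
#' @param geometry 5-station data frame with columns `a`, `b` (m).
#' @param path,geometry_path output files.
#' @return invisibly, the record path.
#' @export
write_tensile <- function(record, geometry, path, geometry_path) {
  write_delim_meta(record[c("time_s", "force_N", "displacement_m")], path,
                   meta = list(L0_m = fmt_num(attr(record, "L0_m"))))
  gdf <- data.frame(station = seq_len(nrow(geometry)),
                    a_m = geometry$a, b_m = geometry$b)
  write_delim_meta(gdf, geometry_path, meta = list(units = "m"))
  invisible(path)
}

#' @rdname write_tensile
#' @export
read_tensile <- function(path, geometry_path) {
  rec <- read_delim_checked(path, c("time_s", "force_N", "displacement_m"))
  meta <- attr(rec, "meta")
  if (is.null(meta$L0_m)) stopf("%s: missing '# L0_m:' header", path)
  attr(rec, "L0_m") <- as.numeric(meta$L0_m)
  g <- read_delim_checked(geometry_path, c("station", "a_m", "b_m"))
  list(record = rec, geometry = data.frame(a = g$a_m, b = g$b_m))
}

rm_columns <- c("subject", "condition", "time_min", "gamma_deg")

#' Write / read a repeated-measures bending-angle table
#'
#' Long-format dialect `subject, condition, time_min, gamma_deg` (degrees);
#' duplicated (subject, condition, time) keys are rejected on read.
#'
#' @param table the long-format table.
#' @param path file path.
#' @return the table (read) or the path, invisibly (write).
#' @export
write_rm_table <- function(table, path) {
  write_delim_meta(table[rm_columns], path,
                   meta = list(units = "gamma_deg in degrees, time in minutes"))
  invisible(path)
}

#' @rdname write_rm_table
#' @export
read_rm_table <- function(path) {
  df <- read_delim_checked(path, rm_columns)
  validate_rm_table(df)
  df
}

#' Write a results report
#'
#' Emits a machine-readable JSON report and a plain-text summary of the
#' condition x time median table and the repeated-measures inference.
#'
#' @param results a list as returned by [run_pipeline()].
#' @param dir output directory.
#' @return invisibly, the JSON path.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  payload <- list(
    medians_deg = results$medians,
    anova = list(effects = results$anova$effects,
                 sphericity = results$anova$sphericity,
                 ranks = results$anova$ranks),
    pairwise = results$pairwise,
    manifest = results$manifest)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  cat("Wound self-sealing analysis report\n")
  cat("==================================\n\n")
  cat("Median relative bending angle (degrees) by condition x time:\n")
  print(results$medians, row.names = FALSE)
  cat("\n")
  print(results$anova)
  cat("\nPairwise Bonferroni t-tests (condition):\n")
  print(results$pairwise$condition, row.names = FALSE)
  cat("\nPairwise Bonferroni t-tests (time):\n")
  print(results$pairwise$time, row.names = FALSE)
  invisible(json_path)
}
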