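#' Controlled organ vocabulary
#'
#' Rodent VOI labels are mapped onto a controlled vocabulary of phantom
#' compartment names before any dosimetry arithmetic. Paired organs (left and
#' right kidneys, left and right lungs) map onto a single compartment and
#' their activities are summed at read time. Unknown labels are an error,
#' never silently dropped.
#'
#' @return Named character vector: names are accepted input labels
#'   (lower-case), values are canonical compartment names.
#' @export
organ_vocabulary <- function() {
  c(
    "kidneys"                     = "kidneys",
    "kidney"                      = "kidneys",
    "left kidney"                 = "kidneys",
    "right kidney"                = "kidneys",
    "lungs"                       = "lungs",
    "lung"                        = "lungs",
    "left lung"                   = "lungs",
    "right lung"                  = "lungs",
    "urinary bladder"             = "urinary bladder",
    "bladder"                     = "urinary bladder",
    "heart"                       = "heart",
    "brain"                       = "brain",
    "liver"                       = "liver",
    "intestine"                   = "intestine",
    "intestines"                  = "intestine",
    "lli wall"                    = "LLI wall",
    "lower large intestine wall"  = "LLI wall",
    "spleen"                      = "spleen",
    "whole_body"                  = "whole_body",
    "whole body"                  = "whole_body",
    "whole-body"                  = "whole_body",
    "remainder"                   = "remainder",
    "remaining"                   = "remainder",
    "remainder of body"           = "remainder"
  )
}

#' Map an organ label onto the controlled vocabulary
#'
#' @param x Character vector of organ labels as found in input files.
#' @return Canonical compartment names.
#' @export
canonical_organ <- function(x) {
  voc <- organ_vocabulary()
  key <- tolower(trimws(x))
  hit <- voc[key]
  if (anyNA(hit)) {
    bad <- unique(x[is.na(hit)])
    stop("unknown organ name: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(hit)
}

## Minutes are the file/time unit; residence times are hours. All
## minute->hour conversion funnels through here so the factor exists once.
minutes_to_hours <- function(t_min) t_min / 60

#' Time-activity curve for one organ
#'
#' Holds one organ's sampled activity over the scan frames of a single
#' subject. Activity is expressed as percent of injected dose (%ID); frames
#' carry start and end times in minutes (midpoints are derived where needed).
#'
#' @param organ Canonical compartment name (see [organ_vocabulary()]).
#' @param frames Data frame with columns `t_start`, `t_end` (minutes) and
#'   `activity` (%ID), ordered and non-overlapping.
#' @param decay_corrected Logical; `TRUE` if the activities have been
#'   corrected back to injection time (physical decay removed).
#' @param injected_activity Optional injected activity in MBq (metadata only;
#'   activities are already fractions of it).
#' @return Object of class `tac`.
#' @export
tac <- function(organ, frames, decay_corrected = FALSE,
                injected_activity = NULL) {
  stopifnot(is.character(organ), length(organ) == 1L)
  frames <- as.data.frame(frames)
  need <- c("t_start", "t_end", "activity")
  if (!all(need %in% names(frames)))
    stop("frames must have columns t_start, t_end, activity", call. = FALSE)
  frames <- frames[need]
  frames[] <- lapply(frames, as.numeric)  # CSV readers may yield integers
  validate_frames(frames, organ)
  structure(
    list(organ = organ, frames = frames,
         decay_corrected = isTRUE(decay_corrected),
         injected_activity = injected_activity),
    class = "tac"
  )
}

validate_frames <- function(frames, organ = "?") {
  if (nrow(frames) < 1L)
    stop("empty frame set for organ ", organ, call. = FALSE)
  if (any(frames$activity < 0))
    stop("negative activity in organ ", organ, call. = FALSE)
  if (any(frames$t_end <= frames$t_start))
    stop("frame with non-positive duration in organ ", organ, call. = FALSE)
  n <- nrow(frames)
  if (n > 1L && any(frames$t_end[-n] > frames$t_start[-1L] + 1e-9))
    stop("overlapping frames in organ ", organ, call. = FALSE)
  invisible(frames)
}

#' Frame midpoints in minutes
#'
#' @param x A `tac` or a frame data frame with `t_start`/`t_end` columns.
#' @return Numeric vector of frame midpoints (minutes).
#' @export
frame_midpoints <- function(x) {
  f <- if (inherits(x, "tac")) x$frames else x
  (f$t_start + f$t_end) / 2
}

#' Default whole-body frame schedule
#'
#' The acquisition re-bins list data as 7 x 1 min, 2 x 5 min and 4 x 10 min
#' (57 min). That template does not span the full scan, so 10-min frames are
#' appended until `total_min` is reached; a final shorter frame closes the
#' schedule exactly at `total_min`.
#'
#' @param total_min Total scan length in minutes (default 240).
#' @return Data frame with `t_start`, `t_end` columns (minutes).
#' @export
default_frame_schedule <- function(total_min = 240) {
  durations <- c(rep(1, 7), rep(5, 2), rep(10, 4))
  if (sum(durations) > total_min)
    stop("total_min shorter than the re-binning template", call. = FALSE)
  while (sum(durations) < total_min)
    durations <- c(durations, min(10, total_min - sum(durations)))
  ends <- cumsum(durations)
  data.frame(t_start = c(0, ends[-length(ends)]), t_end = ends)
}

#' Whole-body scan of one subject
#'
#' Bundles the source-organ time-activity curves and the whole-body curve of
#' one animal, with acquisition metadata. All curves must share one frame
#' schedule. For a non-decay-corrected scan the whole-body activity may not
#' exceed 100 %ID beyond a 5% measurement tolerance.
#'
#' @param subject_id Identifier string.
#' @param radiotracer Radiotracer label.
#' @param body_mass Body mass in grams.
#' @param tacs Named list of source-organ [tac()] objects.
#' @param whole_body Whole-body [tac()].
#' @param reconstruction `"FBP"` or `"iterative"`.
#' @return Object of class `subject_scan`.
#' @export
subject_scan <- function(subject_id, radiotracer, body_mass, tacs,
                         whole_body, reconstruction = c("FBP", "iterative")) {
  reconstruction <- match.arg(reconstruction)
  if (!inherits(whole_body, "tac") || whole_body$organ != "whole_body")
    stop("no whole-body curve", call. = FALSE)
  if (length(tacs) < 1L)
    stop("scan needs at least one source-organ curve", call. = FALSE)
  if (is.null(names(tacs)) || any(names(tacs) == ""))
    names(tacs) <- vapply(tacs, function(t) t$organ, character(1))
  sched <- whole_body$frames[c("t_start", "t_end")]
  for (tc in tacs) {
    if (!inherits(tc, "tac")) stop("tacs must be tac objects", call. = FALSE)
    if (!isTRUE(all.equal(tc$frames[c("t_start", "t_end")], sched,
                          check.attributes = FALSE)))
      stop("inconsistent frame schedule across organs", call. = FALSE)
  }
  if (!whole_body$decay_corrected &&
      any(whole_body$frames$activity > 100 * 1.05))
    stop("whole-body activity exceeds 100 %ID beyond measurement tolerance",
         call. = FALSE)
  structure(
    list(subject_id = subject_id, radiotracer = radiotracer,
         body_mass = body_mass, tacs = tacs, whole_body = whole_body,
         reconstruction = reconstruction),
    class = "subject_scan"
  )
}

#' @export
print.subject_scan <- function(x, ...) {
  cat("<subject_scan>", x$subject_id, "-", x$radiotracer, "\n")
  cat("  reconstruction:", x$reconstruction,
      " body mass:", x$body_mass, "g\n")
  cat("  source organs:", paste(names(x$tacs), collapse = ", "), "\n")
  cat("  frames:", nrow(x$whole_body$frames),
      " span:", max(x$whole_body$frames$t_end), "min\n")
  invisible(x)
}

#' Organ-mass table for a reference subject or phantom
#'
#' @param species Species/phantom label (e.g. `"rat"`, `"adult male"`).
#' @param body_mass Total body mass in grams.
#' @param organ_masses Named numeric vector of organ masses in grams.
#' @return Object of class `organ_mass_table`.
#' @export
organ_mass_table <- function(species, body_mass, organ_masses) {
  stopifnot(is.numeric(body_mass), length(body_mass) == 1L)
  if (body_mass <= 0 || any(organ_masses <= 0))
    stop("non-positive mass", call. = FALSE)
  if (sum(organ_masses) > body_mass)
    stop("organ masses sum above body mass", call. = FALSE)
  if (anyDuplicated(names(organ_masses)))
    stop("duplicate organ name in mass table", call. = FALSE)
  structure(list(species = species, body_mass = body_mass,
                 organ_masses = organ_masses),
            class = "organ_mass_table")
}

#' Phantom S-value matrix with tissue weighting factors
#'
#' S(target <- source) gives the absorbed dose in a target organ per unit
#' cumulated activity in a source organ, in mGy/(MBq h). The matrix is stored
#' target row by source column; `"remainder"` is an ordinary source column.
#' Tissue weighting factors w_T must sum to 1.
#'
#' @param phantom Phantom label (`"adult male"` or `"adult female"`).
#' @param S Numeric matrix, rownames = targets, colnames = sources.
#' @param tissue_weights Named numeric vector of w_T over (a subset of) the
#'   targets, summing to 1.
#' @return Object of class `svalue_matrix`.
#' @export
svalue_matrix <- function(phantom, S, tissue_weights) {
  S <- as.matrix(S)
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("S matrix needs target rownames and source colnames", call. = FALSE)
  if (anyDuplicated(rownames(S)) || anyDuplicated(colnames(S)))
    stop("duplicate organ name in S-value matrix", call. = FALSE)
  if (any(S < 0)) stop("negative S-value", call. = FALSE)
  w <- tissue_weights
  if (is.null(names(w)) || anyDuplicated(names(w)))
    stop("tissue weights must be uniquely named", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9)
    stop(sprintf("weights sum %.6g != 1", sum(w)), call. = FALSE)
  if (!all(names(w) %in% rownames(S)))
    stop("tissue weight for unknown target: ",
         paste(setdiff(names(w), rownames(S)), collapse = ", "),
         call. = FALSE)
  structure(list(phantom = phantom, S = S, tissue_weights = w),
            class = "svalue_matrix")
}

## full-precision numeric formatting so CSV round-trips are bit-exact
fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Read a subject scan from a TAC file
#'
#' The TAC file is a CSV with columns `organ,t_start_min,t_end_min,pct_id`
#' (lines starting with `#` are comments). Scan metadata lives in a YAML
#' sidecar `<path stem>.yaml` with keys `subject_id`, `radiotracer`,
#' `body_mass_g`, `reconstruction`, `decay_corrected`. Organ labels are run
#' through [canonical_organ()]; rows mapping to the same compartment (left +
#' right kidney) are summed frame-wise.
#'
#' @param path Path to the TAC CSV.
#' @param sidecar Path to the metadata YAML; defaults to the CSV path with a
#'   `.yaml` extension.
#' @return A [subject_scan()].
#' @export
read_tac_file <- function(path, sidecar = NULL) {
  if (is.null(sidecar))
    sidecar <- paste0(tools::file_path_sans_ext(path), ".yaml")
  if (!file.exists(sidecar))
    stop("metadata sidecar not found: ", sidecar, call. = FALSE)
  meta <- yaml::read_yaml(sidecar)
  need <- c("subject_id", "radiotracer", "body_mass_g", "reconstruction",
            "decay_corrected")
  if (!all(need %in% names(meta)))
    stop("sidecar missing keys: ",
         paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need_cols <- c("organ", "t_start_min", "t_end_min", "pct_id")
  if (!all(need_cols %in% names(df)))
    stop("TAC file must have columns organ,t_start_min,t_end_min,pct_id",
         call. = FALSE)
  df$organ <- canonical_organ(df$organ)

  split_frames <- lapply(split(df, df$organ), function(d) {
    d <- d[order(d$t_start_min), ]
    ## paired organs arrive as duplicated schedules: sum activity per frame
    agg <- stats::aggregate(pct_id ~ t_start_min + t_end_min, data = d, sum)
    agg <- agg[order(agg$t_start_min), ]
    data.frame(t_start = agg$t_start_min, t_end = agg$t_end_min,
               activity = agg$pct_id)
  })
  if (!"whole_body" %in% names(split_frames))
    stop("no whole-body curve", call. = FALSE)

  dc <- isTRUE(meta$decay_corrected)
  mk <- function(org) tac(org, split_frames[[org]], decay_corrected = dc)
  organs <- setdiff(names(split_frames), c("whole_body", "remainder"))
  if (length(organs) < 1L)
    stop("scan needs at least one source-organ curve", call. = FALSE)
  subject_scan(
    subject_id = as.character(meta$subject_id),
    radiotracer = as.character(meta$radiotracer),
    body_mass = as.numeric(meta$body_mass_g),
    tacs = lapply(stats::setNames(organs, organs), mk),
    whole_body = mk("whole_body"),
    reconstruction = match.arg(meta$reconstruction, c("FBP", "iterative"))
  )
}

#' Write a subject scan to a TAC file (plus YAML sidecar)
#'
#' Values are serialised at full double precision so
#' `read_tac_file(write_tac_file(x))` reproduces activities bit-exactly.
#'
#' @param scan A [subject_scan()].
#' @param path Output CSV path; the sidecar goes to `<path stem>.yaml`.
#' @param comment Optional comment lines (without `#`) written at the top.
#' @return `path`, invisibly.
#' @export
write_tac_file <- function(scan, path, comment = NULL) {
  stopifnot(inherits(scan, "subject_scan"))
  all_tacs <- c(scan$tacs, list(whole_body = scan$whole_body))
  rows <- do.call(rbind, lapply(all_tacs, function(tc) {
    data.frame(organ = tc$organ,
               t_start_min = fmt_num(tc$frames$t_start),
               t_end_min = fmt_num(tc$frames$t_end),
               pct_id = fmt_num(tc$frames$activity))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(
    list(subject_id = scan$subject_id, radiotracer = scan$radiotracer,
         body_mass_g = scan$body_mass, reconstruction = scan$reconstruction,
         decay_corrected = scan$whole_body$decay_corrected),
    paste0(tools::file_path_sans_ext(path), ".yaml"))
  invisible(path)
}

#' Read an S-value matrix and tissue weights
#'
#' The matrix CSV has a `target` first column and one column per source organ
#' (including `remainder`), entries in mGy/(MBq h). The weights CSV has
#' columns `organ,w_T`. Source/target headers are matched verbatim against
#' residence-time organ names.
#'
#' @param path Matrix CSV path.
#' @param weights_path Tissue-weight CSV path.
#' @param phantom Phantom label stored on the object.
#' @return An [svalue_matrix()].
#' @export
read_svalue_matrix <- function(path, weights_path, phantom = "adult male") {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "target")
    stop("S-value matrix must have a 'target' first column", call. = FALSE)
  S <- as.matrix(df[, -1, drop = FALSE])
  rownames(S) <- df$target
  wdf <- utils::read.csv(weights_path, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (!all(c("organ", "w_T") %in% names(wdf)))
    stop("weights file must have columns organ,w_T", call. = FALSE)
  svalue_matrix(phantom, S, stats::setNames(wdf$w_T, wdf$organ))
}

#' Write an S-value matrix and its tissue weights
#'
#' @param sv An [svalue_matrix()].
#' @param path Matrix CSV path.
#' @param weights_path Tissue-weight CSV path.
#' @param comment Optional comment line written at the top of both files.
#' @return `path`, invisibly.
#' @export
write_svalue_matrix <- function(sv, path, weights_path, comment = NULL) {
  stopifnot(inherits(sv, "svalue_matrix"))
  df <- data.frame(target = rownames(sv$S), check.names = FALSE)
  for (src in colnames(sv$S)) df[[src]] <- fmt_num(sv$S[, src])
  write_csv_commented(df, path, comment)
  wdf <- data.frame(organ = names(sv$tissue_weights),
                    w_T = fmt_num(sv$tissue_weights))
  write_csv_commented(wdf, weights_path, comment)
  invisible(path)
}

write_csv_commented <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Read an organ-mass table
#'
#' CSV with columns `organ,mass_g`; metadata in comment lines
#' `# species: <label>` and `# body_mass_g: <grams>`.
#'
#' @param path CSV path.
#' @return An [organ_mass_table()].
#' @export
read_organ_masses <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), meta, value = TRUE)
    if (length(hit) == 0)
      stop("organ-mass file missing '# ", key, ":' metadata line",
           call. = FALSE)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1]))
  }
  df <- utils::read.csv(textConnection(lines), comment.char = "#",
                        stringsAsFactors = FALSE)
  organ_mass_table(species = get_meta("species"),
                   body_mass = as.numeric(get_meta("body_mass_g")),
                   organ_masses = stats::setNames(df$mass_g, df$organ))
}

#' Write an organ-mass table
#'
#' @param tab An [organ_mass_table()].
#' @param path Output CSV path.
#' @param comment Optional extra comment line.
#' @return `path`, invisibly.
#' @export
write_organ_masses <- function(tab, path, comment = NULL) {
  stopifnot(inherits(tab, "organ_mass_table"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(c(paste0("# species: ", tab$species),
               paste0("# body_mass_g: ", fmt_num(tab$body_mass))), con)
  utils::write.csv(
    data.frame(organ = names(tab$organ_masses),
               mass_g = fmt_num(tab$organ_masses)),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an organ dose table
#'
#' CSV with columns `organ,dose_mGy_per_MBq` (clinical reference doses or
#' model predictions).
#'
#' @param path CSV path.
#' @return Named numeric vector of doses (mGy/MBq).
#' @export
read_dose_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("organ", "dose_mGy_per_MBq") %in% names(df)))
    stop("dose table must have columns organ,dose_mGy_per_MBq", call. = FALSE)
  if (anyDuplicated(df$organ))
    stop("duplicate organ name in dose table", call. = FALSE)
  stats::setNames(df$dose_mGy_per_MBq, df$organ)
}

#' Write an organ dose table
#'
#' @param doses Named numeric vector of doses (mGy/MBq).
#' @param path Output CSV path.
#' @param comment Optional comment line.
#' @return `path`, invisibly.
#' @export
write_dose_table <- function(doses, path, comment = NULL) {
  write_csv_commented(
    data.frame(organ = names(doses), dose_mGy_per_MBq = fmt_num(doses)),
    path, comment)
  invisible(path)
}
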