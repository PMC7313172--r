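# ---- well coordinates -------------------------------------------------------

PLATE_ROWS <- LETTERS[1:16]   # A..P
PLATE_COLS <- 1:24

CONTROL_ROLES <- c("negative_dmso", "proliferation_hydroxyurea",
                   "positive_staurosporine", "treated")
CHANNELS <- c("luminescence", "nuclei_count")
TECHNIQUES <- c("enzymatic_2d", "imaging_2d", "imaging_3d")

#' All 384 well labels of a microplate in row-major order
#'
#' @return character vector "A1".."P24" (row-major: A1, A2, ..., A24, B1, ...)
#' @export
well_labels_384 <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
}

#' Validate 384-well coordinates
#'
#' Accepts row letter A-P followed by column 1-24 (no leading zeros required;
#' "A01" is normalized to "A1").
#'
#' @param well character vector of well labels
#' @return normalized well labels
#' @export
validate_wells <- function(well) {
  well <- toupper(trimws(well))
  m <- regmatches(well, regexec("^([A-Z])0*([0-9]{1,2})$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (!any(bad)) {
    row <- vapply(m, `[`, "", 2L)
    col <- as.integer(vapply(m, `[`, "", 3L))
    bad <- !(row %in% PLATE_ROWS) | col < 1L | col > 24L
  }
  if (any(bad)) {
    stop("malformed or out-of-range well coordinate(s): ",
         paste(unique(well[bad]), collapse = ", "), call. = FALSE)
  }
  paste0(vapply(m, `[`, "", 2L), as.integer(vapply(m, `[`, "", 3L)))
}

# ---- DoseSeries -------------------------------------------------------------

#' Construct a dilution series
#'
#' A descending geometric dose series: \code{top_dose / fold^(0:(n_doses-1))},
#' in micromolar.
#'
#' @param top_dose highest dose (uM), positive
#' @param fold dilution factor, > 1
#' @param n_doses number of doses, >= 1
#' @return object of class \code{dose_series} with \code{$doses} descending
#' @examples
#' dose_series(5, 2, 3)$doses  # 5.00 2.50 1.25
#' @export
dose_series <- function(top_dose, fold, n_doses) {
  stopifnot(is.numeric(top_dose), top_dose > 0,
            is.numeric(fold), fold > 1,
            n_doses >= 1, n_doses == as.integer(n_doses))
  structure(list(top_dose = top_dose, fold = fold,
                 n_doses = as.integer(n_doses),
                 doses = top_dose / fold^(0:(n_doses - 1L))),
            class = "dose_series")
}

# ---- ScreenTable ------------------------------------------------------------

#' Build a validated screen table
#'
#' The universal interchange record: one row per well with plate, coordinates,
#' compound, dose (uM), readout channel, signal and control role.
#'
#' @param df data.frame with columns plate_id, well, compound_id, dose_uM,
#'   channel, signal, role
#' @return the validated data.frame with class \code{screen_table}
#' @export
screen_table <- function(df) {
  req <- c("plate_id", "well", "compound_id", "dose_uM", "channel",
           "signal", "role")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("screen table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[req]
  df$well <- validate_wells(df$well)
  if (!all(df$role %in% CONTROL_ROLES))
    stop("unknown control role(s): ",
         paste(setdiff(unique(df$role), CONTROL_ROLES), collapse = ", "),
         call. = FALSE)
  if (!all(df$channel %in% CHANNELS))
    stop("unknown channel(s): ",
         paste(setdiff(unique(df$channel), CHANNELS), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$signal)) || any(df$signal < 0))
    stop("signals must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(df$dose_uM)) || any(df$dose_uM < 0))
    stop("doses must be finite and non-negative", call. = FALSE)
  key <- paste(df$plate_id, df$well, df$channel)
  if (anyDuplicated(key))
    stop("duplicate (plate, well) entries: ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "),
         call. = FALSE)
  n_per_plate <- table(paste(df$plate_id, df$channel))
  if (any(n_per_plate > 384))
    stop("more than 384 wells on a plate", call. = FALSE)
  # dose must be 0 exactly on control wells, positive on treated wells
  ctrl <- df$role != "treated"
  if (any(df$dose_uM[ctrl] != 0))
    stop("control wells must carry dose 0", call. = FALSE)
  if (any(df$dose_uM[!ctrl] <= 0))
    stop("treated wells must carry a positive dose", call. = FALSE)
  class(df) <- c("screen_table", "data.frame")
  df
}

#' Read a screen table from a readout CSV and a plate map
#'
#' The readout CSV carries \code{plate_id, well, compound_id, dose_uM,
#' channel, signal}; the plate map carries \code{plate_id, well, role,
#' compound_id, dose_uM}. Control roles come from the map. Readout wells
#' absent from the map are accepted as \code{treated} only when they carry a
#' compound and a positive dose. An optional \code{dose_unit} column with
#' values "uM" or "nM" is honoured (nM converted at the boundary).
#'
#' @param path readout CSV path
#' @param plate_map plate-map CSV path, or NULL if the readout CSV already
#'   carries a \code{role} column
#' @return a \code{screen_table}
#' @export
read_screen_table <- function(path, plate_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("dose_unit" %in% names(df)) {
    nm <- df$dose_unit == "nM"
    df$dose_uM[nm] <- df$dose_uM[nm] / 1000
    df$dose_unit <- NULL
  }
  if (!is.null(plate_map)) {
    pm <- utils::read.csv(plate_map, stringsAsFactors = FALSE)
    pm$well <- validate_wells(pm$well)
    df$well <- validate_wells(df$well)
    key_r <- paste(df$plate_id, df$well)
    key_m <- paste(pm$plate_id, pm$well)
    idx <- match(key_r, key_m)
    role <- pm$role[idx]
    unmapped <- is.na(idx)
    if (any(unmapped)) {
      ok <- !is.na(df$compound_id[unmapped]) &
        nzchar(df$compound_id[unmapped]) & df$dose_uM[unmapped] > 0
      if (!all(ok))
        stop("wells absent from plate map without compound+dose: ",
             paste(utils::head(key_r[unmapped][!ok], 3), collapse = "; "),
             call. = FALSE)
      role[unmapped] <- "treated"
    }
    df$role <- role
  } else if (!("role" %in% names(df))) {
    stop("no plate map given and readout lacks a 'role' column", call. = FALSE)
  }
  df$compound_id[is.na(df$compound_id)] <- ""
  screen_table(df)
}

#' Write a screen table to CSV (UTF-8, "." decimal separator)
#'
#' @param tab a \code{screen_table}
#' @param path output path
#' @export
write_screen_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a compound library manifest
#'
#' Columns: \code{compound_id, name, target_class, library_flag}
#' (\code{fda_approved} or \code{investigational}). \code{target_class} may be
#' empty but the column must exist.
#'
#' @param path manifest CSV path
#' @return data.frame
#' @export
read_library_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- c("compound_id", "name", "target_class", "library_flag")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("manifest missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$compound_id))
    stop("duplicate compound_id in manifest", call. = FALSE)
  if (!all(df$library_flag %in% c("fda_approved", "investigational")))
    stop("library_flag must be fda_approved or investigational", call. = FALSE)
  df$target_class[is.na(df$target_class)] <- ""
  df
}

# ---- AssayRun ---------------------------------------------------------------

#' Bundle a screen table into an assay run
#'
#' @param tab a \code{screen_table}
#' @param technique one of enzymatic_2d, imaging_2d, imaging_3d
#' @param assay_window_T assay duration in hours (default 72)
#' @return object of class \code{assay_run}; control summaries are computed
#'   lazily by \code{\link{summarize_controls}}
#' @export
assay_run <- function(tab, technique, assay_window_T = 72) {
  technique <- match.arg(technique, TECHNIQUES)
  stopifnot(inherits(tab, "screen_table"), assay_window_T > 0)
  run <- structure(list(technique = technique,
                        assay_window_T = assay_window_T,
                        table = tab, plate_controls = NULL,
                        flags = character()),
                   class = "assay_run")
  summarize_controls(run)
}

#' Per-plate control medians
#'
#' Computes the median signal of negative (DMSO), proliferation-stall
#' (hydroxyurea) and positive (staurosporine) control wells for each plate
#' and channel, and stores them on the run. A plate missing a control role is
#' an error; fewer than 8 wells of a role is a warning; a plate where the
#' expected ordering neg >= hu >= pos fails is flagged (not an error).
#'
#' @param run an \code{assay_run}
#' @return the run with \code{$plate_controls} (data.frame: plate_id, channel,
#'   neg_median, hu_median, pos_median, n_neg, n_hu, n_pos, growth_flag)
#' @export
summarize_controls <- function(run) {
  stopifnot(inherits(run, "assay_run"))
  tab <- run$table
  ctrl <- tab[tab$role != "treated", , drop = FALSE]
  out <- list(); flags <- character()
  for (pc in split(ctrl, list(ctrl$plate_id, ctrl$channel), drop = TRUE)) {
    plate <- pc$plate_id[1]; ch <- pc$channel[1]
    med <- function(role) stats::median(pc$signal[pc$role == role])
    n <- function(role) sum(pc$role == role)
    ns <- c(n("negative_dmso"), n("proliferation_hydroxyurea"),
            n("positive_staurosporine"))
    if (any(ns == 0))
      stop("plate ", plate, " (", ch, ") missing a control role entirely",
           call. = FALSE)
    if (any(ns < 8))
      warning("plate ", plate, " (", ch, ") has fewer than 8 wells of a ",
              "control role", call. = FALSE)
    neg <- med("negative_dmso"); hu <- med("proliferation_hydroxyurea")
    pos <- med("positive_staurosporine")
    gf <- !(neg >= hu && hu >= pos)
    if (gf) flags <- c(flags, paste0("plate ", plate, " (", ch,
                                     "): control ordering neg>=hu>=pos violated"))
    out[[length(out) + 1L]] <- data.frame(
      plate_id = plate, channel = ch, neg_median = neg, hu_median = hu,
      pos_median = pos, n_neg = ns[1], n_hu = ns[2], n_pos = ns[3],
      growth_flag = gf, stringsAsFactors = FALSE)
  }
  pcs <- do.call(rbind, out)
  # plates with treated wells must have controls
  treated_plates <- unique(tab$plate_id[tab$role == "treated"])
  missing <- setdiff(treated_plates, pcs$plate_id)
  if (length(missing))
    stop("plate(s) without any control wells: ",
         paste(missing, collapse = ", "), call. = FALSE)
  run$plate_controls <- pcs[order(pcs$plate_id, pcs$channel), ]
  rownames(run$plate_controls) <- NULL
  run$flags <- flags
  run
}

#' @export
print.assay_run <- function(x, ...) {
  cat("<assay_run>", x$technique, "| T =", x$assay_window_T, "h |",
      length(unique(x$table$plate_id)), "plate(s),",
      nrow(x$table), "wells\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
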