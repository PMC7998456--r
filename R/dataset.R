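#' Longitudinal study datasets
#'
#' A `study_dataset` wraps a tibble of dosing and observation records in a
#' NONMEM-like CSV dialect with columns:
#' \describe{
#'   \item{ID}{integer subject identifier}
#'   \item{OCC}{integer occasion (crossover period); 1 for single-occasion designs}
#'   \item{TIME}{time in h; 0 is the 08:00 dose start of day 1 of the occasion}
#'   \item{AMT}{dose amount in mg (0 on observation rows)}
#'   \item{DUR}{infusion duration in h (0 on observation rows)}
#'   \item{DV}{observed value (NA on dose rows)}
#'   \item{DVTYPE}{0 = dose row, 1 = plasma concentration (ng/mL), 2 = intragastric pH}
#'   \item{MDV}{missing-DV flag; 1 on dose rows and non-informative records}
#'   \item{WT}{body weight in kg}
#'   \item{SEX}{1 = male, 0 = female}
#' }
#'
#' @param records tibble/data frame of records in the dialect above
#' @param label dataset label
#' @param manifest optional list of generation metadata (design, seed,
#'   parameter values)
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(records, label = "dataset", manifest = list()) {
  records <- tibble::as_tibble(records)
  validate_records(records)
  records <- records[order(records$ID, records$OCC, records$TIME,
                           records$DVTYPE, -records$AMT), ]
  structure(list(records = records, label = label, manifest = manifest),
            class = "study_dataset")
}

.dataset_columns <- c("ID", "OCC", "TIME", "AMT", "DUR", "DV", "DVTYPE",
                      "MDV", "WT", "SEX")

validate_records <- function(records) {
  missing <- setdiff(.dataset_columns, names(records))
  if (length(missing))
    stop("dataset is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop("invalid dataset rows (", what, "): row ",
           paste(head(idx, 5), collapse = ", "),
           if (length(idx) > 5) " ..." else "", call. = FALSE)
  }
  bad(!is.finite(records$TIME) | records$TIME < 0, "TIME must be >= 0")
  bad(records$AMT < 0, "AMT must be >= 0")
  bad(records$AMT > 0 & records$MDV != 1, "dose rows must have MDV=1")
  bad(records$AMT > 0 & records$DUR <= 0, "dose rows must have DUR>0")
  bad(records$AMT > 0 & records$DVTYPE != 0, "dose rows must have DVTYPE=0")
  bad(records$AMT == 0 & !records$DVTYPE %in% c(1, 2),
      "observation rows must have DVTYPE 1 or 2")
  bad(records$AMT == 0 & records$MDV == 0 & !is.finite(records$DV),
      "observed rows (MDV=0) must carry a finite DV")
  bad(!records$SEX %in% c(0, 1), "SEX must be 0 or 1")
  bad(!is.finite(records$WT) | records$WT <= 0, "WT must be positive")
  key <- paste(records$ID, records$OCC, records$TIME, records$DVTYPE,
               records$AMT)
  bad(duplicated(key), "duplicate (ID, OCC, TIME, DVTYPE, AMT) key")
  invisible(records)
}

#' @export
print.study_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("Study dataset '%s': %d subjects, %d records (%d conc, %d pH, %d dose)\n",
              x$label, length(unique(r$ID)), nrow(r),
              sum(r$DVTYPE == 1 & r$MDV == 0), sum(r$DVTYPE == 2 & r$MDV == 0),
              sum(r$AMT > 0)))
  print(head(r, 8))
  invisible(x)
}

#' @export
as.data.frame.study_dataset <- function(x, ...) as.data.frame(x$records)

#' Read and write the study-dataset CSV dialect
#'
#' `write_dataset()` serializes the records to CSV (UTF-8, `NA` for missing
#' DV); `read_dataset()` parses and validates a file in the same dialect.
#' The pair round-trips losslessly: write-read-write produces byte-identical
#' files. Unknown extra columns are kept with a warning; missing required
#' columns or malformed numeric fields are errors that name the offending
#' rows.
#'
#' @param path file path
#' @param ds a [study_dataset()]
#' @param label label for the returned dataset
#' @return `read_dataset()` returns a `study_dataset`; `write_dataset()`
#'   returns `path` invisibly.
#' @export
read_dataset <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dat <- readr::read_csv(path, col_types = readr::cols(
    ID = readr::col_integer(), OCC = readr::col_integer(),
    TIME = readr::col_double(), AMT = readr::col_double(),
    DUR = readr::col_double(), DV = readr::col_double(),
    DVTYPE = readr::col_integer(), MDV = readr::col_integer(),
    WT = readr::col_double(), SEX = readr::col_integer(),
    .default = readr::col_guess()), progress = FALSE,
    show_col_types = FALSE)
  prob <- readr::problems(dat)
  if (nrow(prob))
    stop("parsing errors in ", path, " at row(s) ",
         paste(head(unique(prob$row), 5), collapse = ", "), call. = FALSE)
  extra <- setdiff(names(dat), .dataset_columns)
  if (length(extra))
    warning("ignoring unknown dataset columns: ",
            paste(extra, collapse = ", "), call. = FALSE)
  study_dataset(dat[.dataset_columns], label = label)
}

#' @rdname read_dataset
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "study_dataset"))
  out <- ds$records
  ## 15 significant digits: effectively lossless for binary doubles and,
  ## unlike shortest-roundtrip formatting, byte-stable under write-read-write
  for (cl in c("TIME", "AMT", "DUR", "DV", "WT")) {
    v <- out[[cl]]
    out[[cl]] <- ifelse(is.na(v), NA_character_, sprintf("%.15g", v))
  }
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Generation manifest of a dataset
#'
#' @param ds a [study_dataset()]
#' @return The manifest list recorded when the dataset was generated (empty
#'   for datasets read from disk).
#' @export
dataset_manifest <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  ds$manifest
}

## Split into the per-subject structure used by simulation-free code paths:
## list(ID, WT, SEX, occs = list(<occ> = list(doses, conc, ph))).
.split_dataset <- function(ds) {
  r <- ds$records
  lapply(split(r, r$ID), function(sub) {
    occs <- lapply(split(sub, sub$OCC), function(so) {
      list(doses = tibble::tibble(
             start_time = so$TIME[so$AMT > 0],
             amount = so$AMT[so$AMT > 0],
             duration = so$DUR[so$AMT > 0]),
           conc = so[so$DVTYPE == 1 & so$MDV == 0, c("TIME", "DV")],
           ph = so[so$DVTYPE == 2 & so$MDV == 0, c("TIME", "DV")])
    })
    list(ID = sub$ID[1L], WT = sub$WT[1L], SEX = sub$SEX[1L], occs = occs)
  })
}
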