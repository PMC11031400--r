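#' @keywords internal
"_PACKAGE"

# 384-well geometry: rows A-P, columns 1-24
PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24

WELL_CONTENTS <- c("drug_dose", "negative_control", "positive_control", "empty")

#' Parse well addresses such as "A1" or "P24"
#'
#' @param well character vector of well addresses (row letter A-P followed by
#'   column number 1-24).
#' @return data.frame with columns `row` (letter) and `col` (integer).
#' @keywords internal
parse_well <- function(well) {
  m <- regmatches(well, regexec("^([A-P])([0-9]{1,2})$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed well address: ", paste(well[bad], collapse = ", "))
  }
  row <- vapply(m, `[`, "", 2L)
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col < 1L | col > 24L)) {
    stop("well column out of range 1-24: ", paste(well[col < 1L | col > 24L], collapse = ", "))
  }
  data.frame(row = row, col = col, stringsAsFactors = FALSE)
}

#' Construct a plate object from a validated well table
#'
#' A plate is one physical 384-well assay: the well layout (drug, dose,
#' replicate, control role), the per-well luminescence readout when present,
#' and screen metadata.
#'
#' @param wells data.frame with columns `well`, `content`, `drug_id`,
#'   `concentration_uM`, `replicate`, `rlu` (rlu may be `NA` before readout).
#' @param plate_id,patient_id identifiers.
#' @param cancer_class `"hematological"` or `"solid"`.
#' @param readout_reagent free-text reagent label.
#' @param received_date,readout_date ISO-8601 dates (or `NA`).
#' @return an object of class `fpm_plate`.
#' @export
fpm_plate <- function(wells, plate_id = "plate1", patient_id = "patient1",
                      cancer_class = c("solid", "hematological"),
                      readout_reagent = "CellTiter-Glo",
                      received_date = NA, readout_date = NA) {
  cancer_class <- match.arg(cancer_class)
  wells <- validate_wells(wells)
  structure(
    list(
      plate_id = plate_id,
      patient_id = patient_id,
      cancer_class = cancer_class,
      readout_reagent = readout_reagent,
      received_date = if (is.na(received_date)) as.Date(NA) else as.Date(received_date),
      readout_date = if (is.na(readout_date)) as.Date(NA) else as.Date(readout_date),
      wells = wells
    ),
    class = "fpm_plate"
  )
}

#' @export
print.fpm_plate <- function(x, ...) {
  n_drug <- sum(x$wells$content == "drug_dose")
  cat(sprintf(
    "<fpm_plate %s> patient %s (%s), %d wells (%d drug, %d neg ctrl, %d pos ctrl)\n",
    x$plate_id, x$patient_id, x$cancer_class, nrow(x$wells), n_drug,
    sum(x$wells$content == "negative_control"),
    sum(x$wells$content == "positive_control")
  ))
  invisible(x)
}

validate_wells <- function(wells) {
  required <- c("well", "content", "drug_id", "concentration_uM", "replicate", "rlu")
  missing <- setdiff(required, names(wells))
  if (length(missing)) stop("well table lacks columns: ", paste(missing, collapse = ", "))
  wells <- wells[required]
  wells$well <- as.character(wells$well)
  wells$content <- as.character(wells$content)
  wells$drug_id <- as.character(wells$drug_id)
  wells$concentration_uM <- as.numeric(wells$concentration_uM)
  wells$replicate <- as.integer(wells$replicate)
  wells$rlu <- as.numeric(wells$rlu)

  if (nrow(wells) > 384L) stop("more than 384 wells on one plate")
  if (anyDuplicated(wells$well)) {
    stop("format error: duplicate well address ",
         paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "))
  }
  addr <- parse_well(wells$well)
  wells$row <- addr$row
  wells$col <- addr$col
  bad_content <- !wells$content %in% WELL_CONTENTS
  if (any(bad_content)) {
    stop("unknown well content: ", paste(unique(wells$content[bad_content]), collapse = ", "))
  }
  dd <- wells$content == "drug_dose"
  if (any(dd & (is.na(wells$drug_id) | wells$drug_id == ""))) {
    stop("drug_dose wells must carry a drug_id")
  }
  if (any(dd & (is.na(wells$concentration_uM) | wells$concentration_uM <= 0))) {
    stop("drug_dose wells must carry a positive concentration")
  }
  ctrl <- wells$content %in% c("negative_control", "positive_control", "empty")
  wells$drug_id[ctrl] <- NA_character_
  wells$concentration_uM[ctrl] <- NA_real_
  if (any(!is.na(wells$rlu) & wells$rlu < 0)) {
    stop("value error: negative RLU readout")
  }
  rownames(wells) <- NULL
  wells[c("well", "row", "col", "content", "drug_id", "concentration_uM", "replicate", "rlu")]
}

#' Read a plate from layout and readout tables
#'
#' The layout CSV has columns `well,content,drug_id,concentration_uM,replicate`;
#' the readout CSV has columns `well,rlu` (relative luminescence units).
#' Every readout well must exist in the layout; layout wells without a readout
#' row carry `NA` luminescence. An optional metadata CSV (`key,value` pairs)
#' carries plate/patient identifiers and dates.
#'
#' @param layout_file path to the layout CSV.
#' @param readout_file optional path to the readout CSV.
#' @param meta_file optional path to a `key,value` metadata CSV.
#' @param ... metadata overrides passed to [fpm_plate()].
#' @return an `fpm_plate`.
#' @export
read_plate <- function(layout_file, readout_file = NULL, meta_file = NULL, ...) {
  layout <- utils::read.csv(layout_file, stringsAsFactors = FALSE,
                            colClasses = c(well = "character"))
  need <- c("well", "content", "drug_id", "concentration_uM", "replicate")
  missing <- setdiff(need, names(layout))
  if (length(missing)) stop("layout lacks columns: ", paste(missing, collapse = ", "))
  layout$rlu <- NA_real_

  if (!is.null(readout_file)) {
    readout <- utils::read.csv(readout_file, stringsAsFactors = FALSE,
                               colClasses = c(well = "character"))
    if (!all(c("well", "rlu") %in% names(readout))) {
      stop("readout lacks columns well,rlu")
    }
    if (anyDuplicated(readout$well)) {
      stop("format error: duplicate well address in readout")
    }
    unknown <- setdiff(readout$well, layout$well)
    if (length(unknown)) {
      stop("consistency error: readout wells missing from layout: ",
           paste(unknown, collapse = ", "))
    }
    idx <- match(layout$well, readout$well)
    layout$rlu <- readout$rlu[idx]
  }

  meta <- list(...)
  if (!is.null(meta_file)) {
    kv <- utils::read.csv(meta_file, stringsAsFactors = FALSE)
    file_meta <- as.list(stats::setNames(kv$value, kv$key))
    # explicit arguments win over the metadata file
    meta <- utils::modifyList(file_meta, meta)
  }
  do.call(fpm_plate, c(list(wells = layout), meta))
}

#' Write a plate back to layout/readout/metadata CSVs
#'
#' Inverse of [read_plate()]: reading the written files reproduces the plate
#' field for field.
#'
#' @param plate an `fpm_plate`.
#' @param layout_file,readout_file,meta_file output paths (`meta_file` and
#'   `readout_file` may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_plate <- function(plate, layout_file, readout_file = NULL, meta_file = NULL) {
  stopifnot(inherits(plate, "fpm_plate"))
  layout <- plate$wells[c("well", "content", "drug_id", "concentration_uM", "replicate")]
  utils::write.csv(layout, layout_file, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(readout_file)) {
    readout <- plate$wells[!is.na(plate$wells$rlu), c("well", "rlu")]
    utils::write.csv(readout, readout_file, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(meta_file)) {
    kv <- data.frame(
      key = c("plate_id", "patient_id", "cancer_class", "readout_reagent",
              "received_date", "readout_date"),
      value = c(plate$plate_id, plate$patient_id, plate$cancer_class,
                plate$readout_reagent, as.character(plate$received_date),
                as.character(plate$readout_date)),
      stringsAsFactors = FALSE
    )
    utils::write.csv(kv, meta_file, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(c(layout = layout_file, readout = readout_file, meta = meta_file))
}

#' Split combination drug identifiers into component agents
#'
#' Combinations are encoded as a single `drug_id` joining agent names with
#' `"+"` in lexicographic order (e.g. `"cyclophosphamide+topotecan"`).
#'
#' @param drug_id character vector.
#' @return list of character vectors of agent names.
#' @export
combination_agents <- function(drug_id) {
  strsplit(drug_id, "+", fixed = TRUE)
}

#' Canonical combination identifier from agent names
#' @param agents character vector of agent names.
#' @return single `drug_id` string with agents sorted lexicographically.
#' @export
combination_id <- function(agents) {
  paste(sort(agents), collapse = "+")
}

#' Group a plate's drug wells into per-drug dose series
#'
#' One series per `drug_id`, wells sorted by concentration. Drugs present at a
#' single concentration are flagged `insufficient` and are excluded from curve
#' fitting but still reported.
#'
#' @param plate an `fpm_plate`.
#' @return list of `fpm_dose_series` objects, each with fields `drug_id`,
#'   `agents`, `concentrations`, `wells` (data.frame) and `insufficient`.
#' @export
extract_dose_series <- function(plate) {
  stopifnot(inherits(plate, "fpm_plate"))
  dd <- plate$wells[plate$wells$content == "drug_dose", , drop = FALSE]
  if (nrow(dd) == 0L) return(list())
  out <- lapply(split(dd, dd$drug_id), function(w) {
    w <- w[order(w$concentration_uM, w$replicate, w$well), , drop = FALSE]
    rownames(w) <- NULL
    conc <- sort(unique(w$concentration_uM))
    structure(
      list(
        drug_id = w$drug_id[1L],
        agents = combination_agents(w$drug_id[1L])[[1L]],
        concentrations = conc,
        wells = w,
        insufficient = length(conc) < 2L
      ),
      class = "fpm_dose_series"
    )
  })
  out[order(names(out))]
}

#' @export
print.fpm_dose_series <- function(x, ...) {
  cat(sprintf(
    "<fpm_dose_series %s> %d wells, %d concentrations [%g, %g] uM%s\n",
    x$drug_id, nrow(x$wells), length(x$concentrations),
    min(x$concentrations), max(x$concentrations),
    if (x$insufficient) " (insufficient series)" else ""
  ))
  invisible(x)
}

#' Read a drug library table
#'
#' Columns: `drug_id,name,class,formulary,cmax_uM`. `cmax_uM` is the maximum
#' clinically achievable plasma concentration used for the actionability gate;
#' it may be empty when no human pharmacokinetic reference exists.
#'
#' @param file CSV path.
#' @return data.frame with one row per drug.
#' @export
read_drug_library <- function(file) {
  lib <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("drug_id", "name", "class", "formulary", "cmax_uM")
  missing <- setdiff(need, names(lib))
  if (length(missing)) stop("drug library lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(lib$drug_id)) stop("duplicate drug_id in library")
  lib$formulary <- as.logical(lib$formulary)
  lib$cmax_uM <- as.numeric(lib$cmax_uM)
  if (any(!is.na(lib$cmax_uM) & lib$cmax_uM <= 0)) stop("cmax_uM must be positive when present")
  lib
}
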