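#' Read one FAERS-format ASCII table
#'
#' Parses a "$"-delimited quarterly extract file with a header row. Column
#' names are lower-cased and mapped through a per-dialect synonym table so
#' both the pre-2014Q3 legacy headers (`ISR`, `CASE`, `GNDR_COD`, `DRUG_SEQ`)
#' and the current ones (`PRIMARYID`, `CASEID`, `SEX`, ...) resolve to one
#' schema. Unknown columns are preserved but ignored downstream. Rows whose
#' field count does not match the header are skipped and tallied in the
#' `rejects` attribute.
#'
#' @param path path to the file.
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`,
#'   `"INDI"`, `"THER"`.
#' @param column_map optional named character vector of extra
#'   `observed -> canonical` header renames, for quarter dialects beyond the
#'   built-in synonyms.
#' @return a tibble of typed records with attributes `rejects` (number of
#'   malformed rows skipped) and `table_kind`.
#' @export
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines(c("PRIMARYID$CASEID$PT", "1001$1$nausea"), file.path(dir, "REAC.txt"))
#' read_faers_table(file.path(dir, "REAC.txt"), "REAC")
read_faers_table <- function(path, table_kind, column_map = NULL) {
  table_kind <- toupper(table_kind)
  check_that(table_kind %in% c("DEMO", "DRUG", "REAC", "OUTC", "INDI", "THER"),
             paste0("unknown table_kind: ", table_kind))
  check_that(file.exists(path), paste0("file not found: ", path),
             class = "faersignal_io_error")

  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("\\$", lines[[1]])) {
    abort(paste0("unparseable header in ", path),
          class = "faersignal_format_error")
  }
  header <- strsplit(lines[[1]], "$", fixed = TRUE)[[1]]
  cols <- tolower(trimws(header))

  synonyms <- c(
    isr = "primaryid", "case" = "caseid", gndr_cod = "sex",
    drug_seq = "drug_seq", dsg_drug_seq = "dsg_drug_seq"
  )
  if (!is.null(column_map)) {
    synonyms <- c(setNames(tolower(unname(column_map)), tolower(names(column_map))),
                  synonyms)
  }
  hit <- cols %in% names(synonyms)
  cols[hit] <- unname(synonyms[cols[hit]])

  body <- lines[-1]
  fields <- strsplit(body, "$", fixed = TRUE)
  nf_expected <- length(cols)
  # strsplit drops trailing empty fields, so validate on the raw separator
  # count and pad short rows back to full width
  sep_count <- lengths(regmatches(body, gregexpr("$", body, fixed = TRUE)))
  ok <- sep_count == nf_expected - 1L
  rejects <- sum(!ok)
  fields <- lapply(fields[ok], `length<-`, nf_expected)
  mat <- if (length(fields)) {
    matrix(unlist(fields, use.names = FALSE), ncol = nf_expected, byrow = TRUE)
  } else {
    matrix(character(), nrow = 0, ncol = nf_expected)
  }
  out <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                   .name_repair = "minimal")
  names(out) <- cols
  out[!is.na(out) & out == ""] <- NA_character_

  out <- type_faers_columns(out, table_kind)
  attr(out, "rejects") <- rejects
  attr(out, "table_kind") <- table_kind
  out
}

# coerce known columns to their domain types; leave unknown columns as text
type_faers_columns <- function(tbl, table_kind) {
  if ("age" %in% names(tbl)) {
    tbl$age <- suppressWarnings(as.numeric(tbl$age))
  }
  for (col in c("drug_seq", "dsg_drug_seq", "indi_drug_seq")) {
    if (col %in% names(tbl)) {
      tbl[[col]] <- suppressWarnings(as.integer(tbl[[col]]))
    }
  }
  if (table_kind == "DRUG" && "role_cod" %in% names(tbl)) {
    tbl$role_cod <- toupper(tbl$role_cod)
  }
  tbl
}

#' Read a directory of FAERS-format tables
#'
#' Convenience wrapper reading `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#' `OUTC.txt`, `INDI.txt` and `THER.txt` from one directory (missing
#' optional tables INDI/OUTC/THER yield empty tibbles).
#'
#' @param dir directory containing the files.
#' @inheritParams read_faers_table
#' @return a `faers_tables` named list with a `rejects` attribute summing
#'   per-table skip tallies.
#' @export
read_faers_dir <- function(dir, column_map = NULL) {
  kinds <- c("DEMO", "DRUG", "REAC", "OUTC", "INDI", "THER")
  required <- c("DEMO", "DRUG", "REAC")
  out <- list()
  rejects <- 0L
  for (k in kinds) {
    path <- file.path(dir, paste0(k, ".txt"))
    if (file.exists(path)) {
      tbl <- read_faers_table(path, k, column_map = column_map)
      rejects <- rejects + attr(tbl, "rejects")
      out[[tolower(k)]] <- tbl
    } else if (k %in% required) {
      abort(paste0("required table missing from ", dir, ": ", k, ".txt"),
            class = "faersignal_io_error")
    } else {
      out[[tolower(k)]] <- tibble(primaryid = character())
    }
  }
  structure(out, rejects = rejects, class = c("faers_tables", "list"))
}
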