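#' @name report_labeling
#' @title Derive medication class and EEG pathology from report text
#'
#' @description
#' Keyword labeling of clinical-style reports: the medication list is read
#' from the `MEDICATIONS:` line (brand and generic names canonicalized), the
#' pathology stratum from the `IMPRESSION:` line. A recording whose report
#' lists more than one medication, or a single unrecognized one, is
#' `excluded` from every classification task to avoid drug-interaction
#' confounds. Negation is deliberately not handled: matching is
#' substring-on-the-medication-line only.
NULL

# brand/generic -> canonical generic name
MEDICATION_LEXICON <- c(
  dilantin = "phenytoin",  phenytoin = "phenytoin",
  keppra = "levetiracetam", levetiracetam = "levetiracetam"
)

#' Parse the medication list from report text
#'
#' Case-insensitive matching on the `MEDICATIONS:` line; brand and generic
#' names map to one canonical generic name (Dilantin/phenytoin ->
#' `"phenytoin"`, Keppra/levetiracetam -> `"levetiracetam"`). Unrecognized
#' drug names are kept verbatim (lower-cased) so the class assignment can
#' exclude them. `"none"` or an empty list yields `character(0)`.
#'
#' @param report_text Report as a single string or character vector of lines.
#' @return Character vector of canonical medication names.
#' @export
parse_medications <- function(report_text) {
  lines <- unlist(strsplit(paste(report_text, collapse = "\n"), "\n"))
  med_line <- grep("^\\s*MEDICATIONS\\s*:", lines, ignore.case = TRUE,
                   value = TRUE)
  if (length(med_line) == 0)
    stop("report has no MEDICATIONS section", call. = FALSE)
  body <- sub("^\\s*MEDICATIONS\\s*:\\s*", "", med_line[1],
              ignore.case = TRUE)
  body <- trimws(tolower(body))
  if (body == "" || body == "none" || body == "no medications")
    return(character(0))
  toks <- trimws(unlist(strsplit(body, "[,;]+")))
  toks <- toks[nzchar(toks)]
  canon <- ifelse(toks %in% names(MEDICATION_LEXICON),
                  MEDICATION_LEXICON[toks], toks)
  unname(canon)
}

#' Assign the medication class from a canonical medication list
#'
#' Pure, permutation-invariant rule: empty -> `"none"`;
#' exactly `"phenytoin"` -> `"dilantin"`; exactly `"levetiracetam"` ->
#' `"keppra"`; two or more medications, or one unrecognized medication ->
#' `"excluded"` (polypharmacy / out-of-scope drug).
#'
#' @param medications Character vector from [parse_medications()].
#' @return One of `"dilantin"`, `"keppra"`, `"none"`, `"excluded"`.
#' @export
assign_medication_class <- function(medications) {
  if (length(medications) == 0) return("none")
  if (length(medications) > 1) return("excluded")
  switch(medications,
         phenytoin = "dilantin",
         levetiracetam = "keppra",
         "excluded")
}

#' Parse the EEG pathology impression
#'
#' Keyword rule on the `IMPRESSION:` section: `"abnormal"` present ->
#' `"abnormal"`; otherwise `"normal"` present -> `"normal"`; otherwise
#' (or with no impression line) `"unknown"`.
#'
#' @param report_text Report text.
#' @return `"normal"`, `"abnormal"` or `"unknown"`.
#' @export
parse_eeg_status <- function(report_text) {
  lines <- unlist(strsplit(paste(report_text, collapse = "\n"), "\n"))
  imp <- grep("^\\s*IMPRESSION\\s*:", lines, ignore.case = TRUE, value = TRUE)
  if (length(imp) == 0) return("unknown")
  body <- tolower(imp[1])
  if (grepl("abnormal", body)) "abnormal"
  else if (grepl("normal", body)) "normal"
  else "unknown"
}

#' Label one report
#'
#' @param report_text Report text.
#' @return List with `medication_class`, `eeg_status`, `age` (or `NA`),
#'   `sex` (`"male"`, `"female"` or `"unknown"`).
#' @export
label_report <- function(report_text) {
  lines <- unlist(strsplit(paste(report_text, collapse = "\n"), "\n"))
  age_line <- grep("^\\s*AGE\\s*:", lines, ignore.case = TRUE, value = TRUE)
  age <- if (length(age_line))
    suppressWarnings(as.integer(sub("^\\s*AGE\\s*:\\s*", "", age_line[1],
                                    ignore.case = TRUE))) else NA_integer_
  sex_line <- grep("^\\s*SEX\\s*:", lines, ignore.case = TRUE, value = TRUE)
  sex <- if (length(sex_line))
    tolower(trimws(sub("^\\s*SEX\\s*:\\s*", "", sex_line[1],
                       ignore.case = TRUE))) else "unknown"
  if (!sex %in% c("male", "female")) sex <- "unknown"
  list(
    medication_class = assign_medication_class(parse_medications(report_text)),
    eeg_status = parse_eeg_status(report_text),
    age = age, sex = sex
  )
}

#' Label a cohort of reports
#'
#' Labels each recording's report independently and returns a labels table.
#' Recordings whose reports lack a `MEDICATIONS` section are dropped with a
#' logged reason; `excluded` recordings are kept in the table (downstream
#' task assembly never uses them) and their count is reported via message.
#'
#' @param cohort A list of entries with `$id` and `$report`
#'   (e.g. from [generate_cohort()]), or a named character vector/list of
#'   report texts.
#' @param quiet Suppress the exclusion-count message.
#' @return Data frame: `recording_id`, `medication_class`, `eeg_status`,
#'   `age`, `sex`.
#' @export
label_cohort <- function(cohort, quiet = FALSE) {
  if (is.character(cohort))
    cohort <- mapply(function(txt, id) list(report = txt, id = id),
                     cohort, names(cohort) %||% seq_along(cohort),
                     SIMPLIFY = FALSE)
  rows <- list(); dropped <- character(0)
  for (e in cohort) {
    lab <- tryCatch(label_report(e$report), error = function(err) NULL)
    if (is.null(lab)) { dropped <- c(dropped, as.character(e$id)); next }
    rows[[length(rows) + 1]] <- data.frame(
      recording_id = as.character(e$id),
      medication_class = lab$medication_class,
      eeg_status = lab$eeg_status,
      age = lab$age, sex = lab$sex, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (!quiet) {
    n_exc <- sum(tab$medication_class == "excluded")
    if (n_exc > 0 || length(dropped) > 0)
      message(sprintf("label_cohort: %d excluded (polypharmacy/unknown drug), %d dropped (unparseable)",
                      n_exc, length(dropped)))
  }
  attr(tab, "dropped") <- dropped
  tab
}
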