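#' Default ICD-9-CM code map for psychotic-event outcomes
#'
#' Maps diagnosis codes to the analysis code groups. The defaults cover the
#' code sets used for the outcome and filter definitions: non-organic
#' psychoses 298.0/298.1/298.3/298.8/298.9 (`psychosis`), hallucinations
#' 780.1 (`hallucination`), and substance misuse/dependence 303--305
#' (`substance`, used as an exclusion filter, not an outcome). The
#' `other_psychotic` group is empty by default and can be populated via a
#' user-supplied map. Codes matching no entry are classified `non_outcome`.
#'
#' @return A list with one character vector of code prefixes/ranges per group:
#'   `psychosis`, `hallucination`, `other_psychotic`, `substance`. Entries of
#'   the form `"303-305"` denote inclusive numeric ranges on the integer part
#'   of the code.
#' @seealso [read_code_map()], [classify_codes()]
#' @export
#' @examples
#' default_code_map()
default_code_map <- function() {
  list(
    psychosis = c("298.0", "298.1", "298.3", "298.8", "298.9"),
    hallucination = "780.1",
    other_psychotic = character(),
    substance = "303-305"
  )
}

#' Read a code map from a YAML file
#'
#' The YAML file holds one key per code group (`psychosis`, `hallucination`,
#' `other_psychotic`, `substance`) with a list of ICD-9-CM codes, code
#' prefixes, or `"lo-hi"` integer ranges. Missing groups fall back to
#' [default_code_map()].
#'
#' @param path Path to a YAML file.
#' @return A code map list as returned by [default_code_map()].
#' @export
read_code_map <- function(path) {
  if (!file.exists(path)) abort(paste0("code map file not found: ", path))
  raw <- yaml::read_yaml(path)
  map <- default_code_map()
  known <- names(map)
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste0("unknown code groups in ", path, ": ", paste(extra, collapse = ", ")))
  }
  for (g in intersect(names(raw), known)) map[[g]] <- as.character(unlist(raw[[g]]))
  map
}

# does each code match a single map entry (exact code, prefix, or range)?
.code_matches <- function(code, entry) {
  if (grepl("^[0-9]+-[0-9]+$", entry)) {
    lohi <- as.integer(strsplit(entry, "-", fixed = TRUE)[[1]])
    intpart <- suppressWarnings(as.integer(sub("\\..*$", "", code)))
    !is.na(intpart) & intpart >= lohi[1] & intpart <= lohi[2]
  } else {
    code == entry | startsWith(code, paste0(entry, "."))
  }
}

#' Classify diagnosis codes into analysis groups
#'
#' Adds a `code_group` column to an event table. Groups are matched in the
#' order psychosis, hallucination, other_psychotic, substance; the first
#' matching group wins, and unmatched codes become `"non_outcome"`.
#'
#' @param events A data frame with an `icd9_code` character column.
#' @param code_map A code map list, see [default_code_map()].
#' @return The input as a tibble with a `code_group` column added.
#' @export
#' @examples
#' classify_codes(tibble::tibble(icd9_code = c("298.9", "780.1", "304.2", "314.00")))
classify_codes <- function(events, code_map = default_code_map()) {
  events <- tibble::as_tibble(events)
  code <- as.character(events$icd9_code)
  group <- rep("non_outcome", length(code))
  # earlier groups take precedence; later groups fill only unset codes
  for (g in c("psychosis", "hallucination", "other_psychotic", "substance")) {
    hit <- Reduce(`|`, lapply(code_map[[g]], .code_matches, code = code), rep(FALSE, length(code)))
    group[group == "non_outcome" & hit] <- g
  }
  events$code_group <- group
  events
}

# tie-break priority for same-day outcome events
.OUTCOME_PRIORITY <- c(psychosis = 1L, hallucination = 2L, other_psychotic = 3L)
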