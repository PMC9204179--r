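# Terminology: a synonym lexicon (surface string -> preferred term code) plus
# a strict 4-level hierarchy PT -> HLT -> HLGT -> SOC, mirroring the structure
# of MedDRA without distributing licensed content. The shipped fixture is
# synthetic (see inst/extdata/terminology_synthetic.csv).

#' Load a terminology from CSV
#'
#' The CSV must have columns `synonym,pt_code,pt_name,hlt_code,hlgt_code,
#' soc_code`. Each preferred term (PT) has exactly one parent high-level term
#' (HLT), each HLT one high-level group term (HLGT), and each HLGT one system
#' organ class (SOC); loading fails atomically if any code has two parents,
#' a synonym maps to two different PTs, or a synonym row names a PT absent
#' from the hierarchy.
#'
#' @param path path to the terminology CSV.
#' @param version version tag stored on the object (default the file name).
#' @return an object of class `pv_terminology` with elements `synonyms`
#'   (tibble: `synonym`, `pt_code`), `hierarchy` (tibble: one row per PT with
#'   `pt_code`, `pt_name`, `hlt_code`, `hlgt_code`, `soc_code`) and `version`.
#' @export
load_terminology <- function(path, version = basename(path)) {
  if (!file.exists(path)) stop("terminology file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("synonym", "pt_code", "pt_name", "hlt_code", "hlgt_code", "soc_code")
  if (!all(needed %in% names(raw))) {
    stop("terminology CSV must have columns ", paste(needed, collapse = ","),
         call. = FALSE)
  }
  raw$synonym <- tolower(trimws(raw$synonym))
  codes <- raw[, c("pt_code", "hlt_code", "hlgt_code", "soc_code")]
  no_path <- !stats::complete.cases(codes) |
    rowSums(codes == "" | is.na(codes)) > 0
  if (any(no_path)) {
    stop("PT without a full hierarchy path: ",
         paste(unique(raw$pt_code[no_path]), collapse = ", "), call. = FALSE)
  }

  dup <- unique(raw$synonym[ave(raw$pt_code, raw$synonym,
                                FUN = function(x) length(unique(x))) > 1])
  if (length(dup)) {
    stop("synonym mapped to more than one PT: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }

  hier <- unique(raw[, c("pt_code", "pt_name", "hlt_code", "hlgt_code", "soc_code")])
  multi_parent <- function(child, parent) {
    bad <- unique(child[ave(parent, child, FUN = function(x) length(unique(x))) > 1])
    if (length(bad)) {
      stop("code with more than one parent: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  multi_parent(hier$pt_code, hier$hlt_code)
  multi_parent(hier$hlt_code, hier$hlgt_code)
  multi_parent(hier$hlgt_code, hier$soc_code)
  if (anyDuplicated(hier$pt_code)) {
    stop("PT code with inconsistent rows: ",
         paste(unique(hier$pt_code[duplicated(hier$pt_code)]), collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(raw$pt_code, hier$pt_code)
  if (length(orphan)) {
    stop("synonym references PT absent from hierarchy: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }

  structure(
    list(
      synonyms  = tibble::as_tibble(unique(raw[, c("synonym", "pt_code")])),
      hierarchy = tibble::as_tibble(hier),
      version   = version
    ),
    class = "pv_terminology"
  )
}

#' @export
print.pv_terminology <- function(x, ...) {
  cat("<pv_terminology> ", x$version, "\n",
      "  ", nrow(x$synonyms), " synonyms -> ", nrow(x$hierarchy), " PTs, ",
      length(unique(x$hierarchy$hlt_code)), " HLTs, ",
      length(unique(x$hierarchy$hlgt_code)), " HLGTs, ",
      length(unique(x$hierarchy$soc_code)), " SOCs\n", sep = "")
  invisible(x)
}

#' Bundled synthetic terminology fixture
#'
#' @return a `pv_terminology` loaded from the synthetic fixture shipped with
#'   the package. The content is invented; only the structure matches a
#'   regulatory terminology.
#' @export
example_terminology <- function() {
  load_terminology(system.file("extdata", "terminology_synthetic.csv",
                               package = "pvforum", mustWork = TRUE),
                   version = "synthetic-1.0")
}

#' Roll a PT code up the hierarchy
#'
#' @param pt_code a PT code present in the terminology.
#' @param level one of `"HLT"`, `"HLGT"`, `"SOC"`.
#' @param term a `pv_terminology`.
#' @return the unique ancestor code at the requested level.
#' @export
roll_up <- function(pt_code, level = c("HLT", "HLGT", "SOC"), term) {
  level <- match.arg(level)
  stopifnot(inherits(term, "pv_terminology"))
  i <- match(pt_code, term$hierarchy$pt_code)
  if (anyNA(i)) {
    stop("unknown PT code: ", paste(pt_code[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  col <- c(HLT = "hlt_code", HLGT = "hlgt_code", SOC = "soc_code")[[level]]
  term$hierarchy[[col]][i]
}
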