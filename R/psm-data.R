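#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

# required columns of the canonical PSM table, in canonical order
psm_required_cols <- c(
  "spectrum_id", "peptide", "charge", "protein_accession",
  "delta_cn", "xcorr", "delta_m", "sp_rank", "perc_ions", "rt_pvalue"
)
psm_optional_cols <- c("raw_prob", "adjusted_prob", "predicted_class")
psm_score_cols <- c("delta_cn", "xcorr", "delta_m", "sp_rank", "perc_ions", "rt_pvalue")

#' Validate a PSM table
#'
#' Checks the structural invariants of the canonical PSM table: required
#' columns present, `spectrum_id` unique, scores in their legal ranges
#' (`perc_ions` and `rt_pvalue` in \[0,1\], `sp_rank >= 1`, `charge >= 1`,
#' `delta_cn` and `xcorr` non-negative), `class_label` consistent with the
#' decoy prefix when one is supplied, and, when `adjusted_prob` and
#' `predicted_class` are both set, the 0.5 decision rule
#' (`predicted_class == 1` iff `adjusted_prob >= 0.5`).
#'
#' @param psms A data frame with the canonical PSM columns.
#' @param decoy_prefix Optional accession prefix marking decoy hits; when
#'   given, `class_label` is checked against it.
#' @return `psms`, invisibly, as a tibble. Errors describe the first
#'   violated invariant.
#' @export
validate_psms <- function(psms, decoy_prefix = NULL) {
  psms <- tibble::as_tibble(psms)
  missing <- setdiff(psm_required_cols, names(psms))
  if (length(missing) > 0) {
    abort(paste0("PSM table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(psms) == 0) abort("PSM table is empty")
  for (col in psm_score_cols) {
    v <- psms[[col]]
    if (!is.numeric(v)) abort(paste0("column '", col, "' is not numeric"))
    if (anyNA(v)) {
      abort(paste0("column '", col, "' contains NA at row(s) ",
                   paste(utils::head(which(is.na(v)), 5), collapse = ", ")))
    }
  }
  if (anyDuplicated(psms$spectrum_id)) {
    dup <- psms$spectrum_id[duplicated(psms$spectrum_id)][1]
    abort(paste0("duplicated spectrum_id: '", dup, "'"))
  }
  check_range <- function(col, lo, hi = Inf) {
    v <- psms[[col]]
    bad <- which(v < lo | v > hi)
    if (length(bad) > 0) {
      abort(sprintf("column '%s' out of range [%s, %s] at row %d (value %g)",
                    col, format(lo), format(hi), bad[1], v[bad[1]]))
    }
  }
  check_range("perc_ions", 0, 1)
  check_range("rt_pvalue", 0, 1)
  check_range("sp_rank", 1)
  check_range("delta_cn", 0)
  check_range("xcorr", 0)
  if (any(psms$charge < 1)) abort("charge must be a positive integer")
  if (!is.null(decoy_prefix) && "class_label" %in% names(psms)) {
    expect <- ifelse(startsWith(psms$protein_accession, decoy_prefix), 0L, 1L)
    if (!all(psms$class_label == expect)) {
      abort("class_label inconsistent with decoy_prefix on protein_accession")
    }
  }
  if (all(c("adjusted_prob", "predicted_class") %in% names(psms))) {
    idx <- !is.na(psms$adjusted_prob) & !is.na(psms$predicted_class)
    if (any(psms$predicted_class[idx] != as.integer(psms$adjusted_prob[idx] >= 0.5))) {
      abort("predicted_class must be 1 iff adjusted_prob >= 0.5")
    }
  }
  invisible(psms)
}

#' Label decoy hits by accession prefix
#'
#' Derives the 0/1 class label of the target-decoy strategy: a PSM is a
#' decoy hit (class 0) iff its protein accession starts with `decoy_prefix`,
#' and a target hit (class 1) otherwise. The label is a pure function of the
#' accession and the prefix.
#'
#' @param psms A PSM table.
#' @param decoy_prefix Accession prefix marking decoy proteins (default
#'   `"REV_"`, the reversed-sequence convention).
#' @return The table with a `class_label` integer column (0 = decoy,
#'   1 = target) placed after `protein_accession`.
#' @export
label_decoys <- function(psms, decoy_prefix = "REV_") {
  psms <- tibble::as_tibble(psms)
  psms$class_label <- ifelse(startsWith(psms$protein_accession, decoy_prefix), 0L, 1L)
  dplyr::relocate(psms, "class_label", .after = "protein_accession")
}

#' Read a canonical PSM table
#'
#' Reads the tab-separated PSM table (one row per spectrum's best hit) with
#' the fixed header `spectrum_id, peptide, charge, protein_accession,
#' delta_cn, xcorr, delta_m, sp_rank, perc_ions, rt_pvalue` and optional
#' probability columns `raw_prob`, `adjusted_prob`, `predicted_class`.
#' Class labels are derived from `decoy_prefix`; row order is preserved.
#'
#' @inheritParams label_decoys
#' @param path Path to a TSV file.
#' @return A tibble, one row per PSM, with `class_label` set.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_psm_table(simulate_psms(n_targets = 5, n_decoys = 5, seed = 1)$psms, f)
#' read_psm_table(f)
#' @export
read_psm_table <- function(path, decoy_prefix = "REV_") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (file.size(path) == 0) abort(paste0("empty PSM table: ", path))
  spec <- readr::cols(
    spectrum_id = readr::col_character(),
    peptide = readr::col_character(),
    charge = readr::col_integer(),
    protein_accession = readr::col_character(),
    delta_cn = readr::col_double(),
    xcorr = readr::col_double(),
    delta_m = readr::col_double(),
    sp_rank = readr::col_double(),
    perc_ions = readr::col_double(),
    rt_pvalue = readr::col_double(),
    raw_prob = readr::col_double(),
    adjusted_prob = readr::col_double(),
    predicted_class = readr::col_integer(),
    class_label = readr::col_skip()
  )
  # optional columns may be absent; readr warns about their unused parsers
  psms <- withCallingHandlers(
    readr::read_tsv(path, col_types = spec, progress = FALSE,
                    na = character()),
    warning = function(w) {
      if (grepl("named parsers", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (nrow(psms) == 0) abort(paste0("empty PSM table: ", path))
  probs <- readr::problems(psms)
  if (nrow(probs) > 0) {
    # +1: readr reports data rows, the file has a header line
    abort(sprintf("parse error in '%s' at line %d, column '%s': expected %s, got '%s'",
                  path, probs$row[1] + 1L,
                  names(psms)[probs$col[1]], probs$expected[1], probs$actual[1]))
  }
  psms <- label_decoys(psms, decoy_prefix)
  validate_psms(psms, decoy_prefix)
  psms
}

#' Write a canonical PSM table
#'
#' Serializes a PSM table as TSV so that [read_psm_table()] recovers it
#' field-for-field, including any probability columns that are set.
#'
#' @param psms A non-empty PSM table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  psms <- tibble::as_tibble(psms)
  if (nrow(psms) == 0) abort("refusing to write an empty PSM table")
  validate_psms(psms)
  keep <- c(psm_required_cols, "class_label",
            intersect(psm_optional_cols, names(psms)))
  out <- psms[, intersect(union(keep, names(psms)), keep)]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Stratify PSMs by phosphorylation status and precursor charge
#'
#' Partitions a PSM table the way phosphoproteomics target-decoy analyses
#' are run: by whether the peptide carries the phospho modification marker,
#' and by precursor charge state. By default only +2 and +3 precursors are
#' retained; strata with fewer target PSMs than `min_targets` are flagged
#' as too small to model.
#'
#' @param psms A PSM table with `class_label` set.
#' @param phospho_marker Character marking a phosphorylated residue in the
#'   peptide string (default `"*"`, Sequest-style S/T/Y notation).
#' @param charges Charge states retained (default `c(2, 3)`).
#' @param keep_all_charges If `TRUE`, keep every charge state.
#' @param min_targets Strata with fewer target PSMs than this are flagged.
#' @return A tibble with one row per non-empty stratum: `stratum` (named
#'   like `PH_CH2` / `NPH_CH3`), `phospho`, `charge`, `n`, `n_targets`,
#'   `flagged`, and a `data` list-column holding the stratum's PSM table.
#'   Strata are pairwise disjoint and, when all charges are kept, their
#'   union is the input.
#' @export
stratify_psms <- function(psms, phospho_marker = "*", charges = c(2, 3),
                          keep_all_charges = FALSE, min_targets = 10) {
  psms <- tibble::as_tibble(psms)
  if (any(psms$charge < 1)) abort("charge must be >= 1")
  if (!keep_all_charges) psms <- dplyr::filter(psms, .data$charge %in% charges)
  # nest on key copies so the nested tables keep their canonical columns
  psms$`..phospho` <- grepl(phospho_marker, psms$peptide, fixed = TRUE)
  psms$`..charge` <- psms$charge
  out <- psms %>%
    tidyr::nest(data = -c("..phospho", "..charge")) %>%
    dplyr::rename(phospho = "..phospho", charge = "..charge") %>%
    dplyr::arrange(dplyr::desc(.data$phospho), .data$charge) %>%
    dplyr::mutate(
      stratum = paste0(ifelse(.data$phospho, "PH", "NPH"), "_CH", .data$charge),
      n = purrr::map_int(.data$data, nrow),
      n_targets = purrr::map_int(.data$data, ~ sum(.x$class_label == 1L)),
      flagged = .data$n_targets < min_targets
    ) %>%
    dplyr::select("stratum", "phospho", "charge", "n", "n_targets", "flagged", "data")
  out
}

#' Read an OpenMS idXML identification file into the canonical PSM table
#'
#' Minimal reader for OpenMS `<IdXML>` documents: for each
#' `PeptideIdentification` the first (best) `PeptideHit` is taken, and the
#' six canonical scores are pulled from hit attributes and `UserParam`
#' entries according to `score_map`. Spectra missing any mapped score are
#' dropped with a warning.
#'
#' @inheritParams label_decoys
#' @param path Path to an idXML file.
#' @param score_map Named character vector mapping the canonical score
#'   columns to the idXML `UserParam` names emitted by the search adapter.
#' @return A canonical PSM tibble with `class_label` set.
#' @export
read_idxml <- function(path, decoy_prefix = "REV_",
                       score_map = c(delta_cn = "deltacn", xcorr = "XCorr",
                                     delta_m = "MassError", sp_rank = "SpRank",
                                     perc_ions = "PercIons",
                                     rt_pvalue = "predicted_RT_p_value")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  doc <- xml2::read_xml(path)
  pids <- xml2::xml_find_all(doc, ".//PeptideIdentification")
  if (length(pids) == 0) abort("no PeptideIdentification elements found")
  rows <- purrr::imap(pids, function(pid, i) {
    hit <- xml2::xml_find_first(pid, "./PeptideHit")
    if (inherits(hit, "xml_missing")) return(NULL)
    params <- xml2::xml_find_all(hit, "./UserParam")
    pv <- stats::setNames(xml2::xml_attr(params, "value"),
                          xml2::xml_attr(params, "name"))
    sid <- xml2::xml_attr(pid, "spectrum_reference")
    if (is.na(sid)) sid <- paste0("spectrum_", i)
    scores <- purrr::map_dbl(score_map, function(nm) {
      v <- xml2::xml_attr(hit, nm)
      if (is.na(v)) v <- pv[[nm]] %||% NA_character_
      suppressWarnings(as.numeric(v))
    })
    tibble::tibble(
      spectrum_id = sid,
      peptide = xml2::xml_attr(hit, "sequence"),
      charge = as.integer(xml2::xml_attr(hit, "charge")),
      protein_accession = xml2::xml_attr(hit, "protein_refs") %||%
        xml2::xml_attr(hit, "accession"),
      !!!as.list(scores)
    )
  })
  psms <- dplyr::bind_rows(rows)
  bad <- !stats::complete.cases(psms[, names(score_map)])
  if (any(bad)) {
    warn(sprintf("dropping %d spectra missing mapped scores", sum(bad)))
    psms <- psms[!bad, ]
  }
  if (nrow(psms) == 0) abort("no usable PSMs in idXML file")
  psms <- label_decoys(psms, decoy_prefix)
  validate_psms(psms, decoy_prefix)
  psms
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
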