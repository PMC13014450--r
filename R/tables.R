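# Published per-pair salt-bridge frequency tables for the two CheY
# homologues (TmY from T. maritima, EcY from E. coli), replica-averaged at
# five temperatures, shipped as plain-text fixtures. They serve as worked
# examples and as inputs for the formed-pair / network / non-native-bridge
# operations without re-running any simulation.

#' Replica-averaged salt-bridge frequency table of a CheY homologue
#'
#' Returns the published per-pair mean formation frequencies at 302, 328,
#' 374, 400 and 450 K, with the secondary-structure elements each pair
#' connects. Residue numbering follows the crystal structures (PDB 1TMY for
#' TmY, 3CHY for EcY).
#'
#' @param protein `"TmY"` (hyperthermophilic, 15 pairs) or `"EcY"`
#'   (mesophilic, 8 pairs).
#' @param long Return long format with one row per (pair, temperature) and
#'   an `f_mean` column instead of the wide `f_<T>` columns.
#' @return Data frame. Wide format: `basic`, `acidic`, `elements`,
#'   `basic_resid`, `acidic_resid`, `f_302` ... `f_450`. Long format adds
#'   `temperature` and `f_mean`.
#' @export
chey_salt_bridge_table <- function(protein = c("TmY", "EcY"), long = FALSE) {
  protein <- match.arg(protein)
  path <- system.file("extdata", paste0("saltbridge_freq_", protein, ".tsv"),
                      package = "thermotraj", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$basic_resid <- as.integer(sub("^[A-Za-z]+", "", d$basic))
  d$acidic_resid <- as.integer(sub("^[A-Za-z]+", "", d$acidic))
  if (!long) return(d)
  temps <- c(302, 328, 374, 400, 450)
  out <- do.call(rbind, lapply(temps, function(tt) {
    data.frame(basic = d$basic, acidic = d$acidic, elements = d$elements,
               basic_resid = d$basic_resid, acidic_resid = d$acidic_resid,
               temperature = tt, f_mean = d[[paste0("f_", tt)]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Salt-bridge observations of a printed table at one temperature
#'
#' Convenience reshaping of [chey_salt_bridge_table()] into the observation
#' format consumed by [formed_pairs()], [build_networks()] and
#' [detect_nonnative_bridges()].
#'
#' @inheritParams chey_salt_bridge_table
#' @param temperature One of 302, 328, 374, 400, 450 (K).
#' @return Data frame with `basic`, `acidic`, `elements`, resid columns and
#'   `f_mean`.
#' @export
chey_salt_bridge_observations <- function(protein = c("TmY", "EcY"),
                                          temperature = 302) {
  d <- chey_salt_bridge_table(protein, long = TRUE)
  keep <- d[d$temperature == temperature, , drop = FALSE]
  if (!nrow(keep)) stop("no column for temperature ", temperature, " K")
  rownames(keep) <- NULL
  keep
}

#' Secondary-structure element definitions for the CheY homologues
#'
#' Residue ranges (crystal-structure numbering) of the named elements where
#' published; unlisted elements must be supplied by the user.
#'
#' @param protein `"TmY"`, `"EcY"` or `NULL` for both.
#' @return Data frame with columns `protein`, `name`, `chain`, `start`,
#'   `end`, `class`.
#' @export
chey_ss_elements <- function(protein = NULL) {
  path <- system.file("extdata", "ss_elements.tsv", package = "thermotraj",
                      mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(protein)) d <- d[d$protein == protein, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Residue-to-element map from a pair table's element annotations
#'
#' Builds the named residue -> element vector used by
#' [classify_locality()], from the `elements` annotation of a frequency
#' table: a pair annotated with a single element name places both residues
#' in that element; a `"<a>-<b>"` annotation places the basic residue in the
#' second element and the acidic residue in the first (the table convention:
#' elements are listed in residue order of the pair label).
#'
#' @param tbl Wide table from [chey_salt_bridge_table()].
#' @return Named character vector mapping residue labels to element names.
#' @export
element_map_from_table <- function(tbl) {
  out <- character(0)
  for (i in seq_len(nrow(tbl))) {
    parts <- strsplit(tbl$elements[i], "-", fixed = TRUE)[[1]]
    first <- if (tbl$acidic_resid[i] < tbl$basic_resid[i]) tbl$acidic[i] else tbl$basic[i]
    second <- setdiff(c(tbl$acidic[i], tbl$basic[i]), first)
    if (length(parts) == 1L) {
      out[first] <- parts[1]; out[second] <- parts[1]
    } else {
      out[first] <- parts[1]; out[second] <- parts[2]
    }
  }
  out
}
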