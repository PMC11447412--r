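## Classification of KEAP1 protein variants against the stress-sensor
## residue maps, and the fail-safe combinatorics of the oxidative sensor.
##
## KEAP1 carries two distinct sensor systems: an oxidative-stress sensor
## built from four cysteines (Cys226, Cys613 and the redundant Cys622/624
## pair) that form intramolecular disulfides, and an electrophile sensor
## (Cys151, Cys273, Cys288) that forms C-S adducts. The oxidative sensor is
## fail-safe: any two of its three parts (P1 = C226, P2 = C613,
## P3 = C622/624) suffice to form a functional disulfide, so single-residue
## loss is tolerated while loss of two parts abolishes sensing.

AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V")
BASIC_AA <- c("H", "R", "K")

#' Sensor residue map of KEAP1
#'
#' Default residue numbering follows the conventional mouse/human sensor
#' positions; all entries are arguments so species-specific offsets or
#' extended neighbour windows can be supplied without code change.
#'
#' @param oxidative_cys oxidative-stress sensor cysteines.
#' @param oxidative_neighbor_basic named character vector mapping neighbour
#'   positions to their expected basic residue (1-letter code).
#' @param electrophile_cys electrophile sensor cysteines.
#' @param parts list of the redundant oxidative sensor parts; a part is
#'   intact while any of its residues survives.
#' @return an object of class `sensor_map`.
#' @export
keap1_sensor_map <- function(oxidative_cys = c(226, 613, 622, 624),
                             oxidative_neighbor_basic = c("225" = "H",
                                                          "614" = "R"),
                             electrophile_cys = c(151, 273, 288),
                             parts = list(P1 = 226, P2 = 613,
                                          P3 = c(622, 624))) {
  if (length(intersect(oxidative_cys, electrophile_cys)) > 0) {
    stop("oxidative and electrophile sensor sets must be disjoint",
         call. = FALSE)
  }
  if (any(lengths(parts) == 0)) {
    stop("every sensor part must contain at least one residue", call. = FALSE)
  }
  if (!setequal(unlist(parts), oxidative_cys)) {
    stop("sensor parts must partition the oxidative cysteine set",
         call. = FALSE)
  }
  structure(
    list(oxidative_cys = as.integer(oxidative_cys),
         oxidative_neighbor_basic = oxidative_neighbor_basic,
         electrophile_cys = as.integer(electrophile_cys),
         parts = lapply(parts, as.integer)),
    class = "sensor_map"
  )
}

#' @export
print.sensor_map <- function(x, ...) {
  cat("KEAP1 sensor residue map\n")
  cat("  oxidative sensor cysteines :",
      paste0("C", x$oxidative_cys, collapse = ", "), "\n")
  cat("  neighbouring basic residues:",
      paste0(x$oxidative_neighbor_basic, names(x$oxidative_neighbor_basic),
             collapse = ", "), "\n")
  cat("  electrophile sensor cysteines:",
      paste0("C", x$electrophile_cys, collapse = ", "), "\n")
  cat("  fail-safe parts:",
      paste(vapply(names(x$parts), function(p)
        paste0(p, "={", paste0("C", x$parts[[p]], collapse = ","), "}"),
        character(1)), collapse = " "), "\n")
  invisible(x)
}

#' Parse a protein-level substitution in HGVS-style notation
#'
#' Accepts 1- or 3-letter amino-acid codes with an optional `p.` prefix,
#' e.g. `"Cys622Ser"`, `"p.C622S"`, `"His225Tyr"`.
#'
#' @param text a single character string.
#' @return an object of class `keap_variant` with `position`, `ref_aa`,
#'   `alt_aa` (1-letter codes) and optional `allele_freq_panels`.
#' @examples
#' parse_protein_variant("Cys622Ser")
#' @export
parse_protein_variant <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single character string", call. = FALSE)
  }
  s <- sub("^p\\.", "", trimws(text))
  m <- regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z]{1,3})$", s)[[1L]]
  if (m[1L] == -1L) {
    stop(sprintf("cannot parse protein change '%s'", text), call. = FALSE)
  }
  tok <- regmatches(s, regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z]{1,3})$",
                               s))[[1L]]
  to_one <- function(code, where) {
    if (nchar(code) == 1L) {
      code <- toupper(code)
      if (!code %in% AA3) {
        stop(sprintf("unknown amino-acid code '%s' in '%s'", where, text),
             call. = FALSE)
      }
      return(code)
    }
    code3 <- paste0(toupper(substr(code, 1, 1)),
                    tolower(substr(code, 2, nchar(code))))
    if (!code3 %in% names(AA3)) {
      stop(sprintf("unknown amino-acid code '%s' in '%s'", where, text),
           call. = FALSE)
    }
    unname(AA3[[code3]])
  }
  ref <- to_one(tok[2L], tok[2L])
  alt <- to_one(tok[4L], tok[4L])
  if (ref == alt) {
    stop(sprintf("'%s' is synonymous (reference equals alternate)", text),
         call. = FALSE)
  }
  keap_variant(as.integer(tok[3L]), ref, alt)
}

#' @rdname parse_protein_variant
#' @param position 1-based protein residue index.
#' @param ref_aa,alt_aa 1-letter amino-acid codes, distinct.
#' @param allele_freq_panels optional named numeric vector of per-panel
#'   allele frequencies (annotation only).
#' @export
keap_variant <- function(position, ref_aa, alt_aa,
                         allele_freq_panels = NULL) {
  if (!is.numeric(position) || length(position) != 1L || position < 1) {
    stop("`position` must be a positive residue index", call. = FALSE)
  }
  if (!ref_aa %in% AA3 || !alt_aa %in% AA3) {
    stop("amino acids must be 1-letter codes from the 20-letter alphabet",
         call. = FALSE)
  }
  if (ref_aa == alt_aa) stop("ref_aa must differ from alt_aa", call. = FALSE)
  structure(
    list(position = as.integer(position), ref_aa = ref_aa, alt_aa = alt_aa,
         allele_freq_panels = allele_freq_panels),
    class = "keap_variant"
  )
}

#' @export
print.keap_variant <- function(x, ...) {
  cat(sprintf("KEAP1 variant %s%d%s\n", x$ref_aa, x$position, x$alt_aa))
  if (!is.null(x$allele_freq_panels)) {
    cat("  allele frequencies:",
        paste(sprintf("%s=%.3g", names(x$allele_freq_panels),
                      x$allele_freq_panels), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
format.keap_variant <- function(x, ...) {
  sprintf("%s%d%s", x$ref_aa, x$position, x$alt_aa)
}

#' Classify a variant against the sensor residue map
#'
#' Category is determined by position lookup: oxidative sensor cysteine,
#' basic neighbour of an oxidative sensor, electrophile sensor cysteine, or
#' non-sensor. A variant whose reference residue contradicts the map (e.g.
#' a non-Cys reference at a sensor-cysteine position) is classified
#' non-sensor with a warning, tolerating annotation drift.
#'
#' @param variant a `keap_variant`.
#' @param map a [keap1_sensor_map()].
#' @return an object of class `variant_classification` with `category`,
#'   `destroys_thiol` (Cys reference replaced by a non-thiol residue) and
#'   `destroys_basicity` (basic reference replaced by a non-basic residue).
#' @export
classify_variant <- function(variant, map = keap1_sensor_map()) {
  stopifnot(inherits(variant, "keap_variant"), inherits(map, "sensor_map"))
  pos <- variant$position
  expected <- NULL
  category <- "non_sensor"
  if (pos %in% map$oxidative_cys) {
    category <- "oxidative_sensor_cys"
    expected <- "C"
  } else if (as.character(pos) %in% names(map$oxidative_neighbor_basic)) {
    category <- "oxidative_neighbor_basic"
    expected <- map$oxidative_neighbor_basic[[as.character(pos)]]
  } else if (pos %in% map$electrophile_cys) {
    category <- "electrophile_sensor_cys"
    expected <- "C"
  }
  if (!is.null(expected) && variant$ref_aa != expected) {
    warning(sprintf(
      "variant %s: reference residue disagrees with the sensor map (%s expected at %d); classifying as non_sensor",
      format(variant), expected, pos), call. = FALSE)
    category <- "non_sensor"
  }
  structure(
    list(
      category = category,
      destroys_thiol = variant$ref_aa == "C" && variant$alt_aa != "C",
      destroys_basicity = variant$ref_aa %in% BASIC_AA &&
        !(variant$alt_aa %in% BASIC_AA),
      variant = variant
    ),
    class = "variant_classification"
  )
}

#' @export
print.variant_classification <- function(x, ...) {
  cat(sprintf("%s: %s%s%s\n", format(x$variant), x$category,
              if (x$destroys_thiol) " (destroys thiol)" else "",
              if (x$destroys_basicity) " (destroys basicity)" else ""))
  invisible(x)
}

#' Fail-safe state of the oxidative stress sensor
#'
#' The oxidative sensor has three redundant parts (by default P1 = C226,
#' P2 = C613, P3 = C622/C624); any two intact parts can still form the
#' functional disulfide. A part is intact while at least one of its
#' residues survives.
#'
#' @param lost_residues integer vector of lost residue positions; positions
#'   outside the oxidative cysteine set are ignored with a warning.
#' @param map a [keap1_sensor_map()].
#' @return an object of class `failsafe_state` with `lost_residues`,
#'   `intact_parts`, `viable_pairs` and `functional`.
#' @examples
#' failsafe_oxidative(c(226, 613))  # both remaining in one part: dead
#' failsafe_oxidative(622)          # C624 rescues part P3: functional
#' @export
failsafe_oxidative <- function(lost_residues = integer(),
                               map = keap1_sensor_map()) {
  stopifnot(inherits(map, "sensor_map"))
  lost <- unique(as.integer(lost_residues))
  extraneous <- setdiff(lost, map$oxidative_cys)
  if (length(extraneous) > 0) {
    warning("ignoring residues outside the oxidative sensor cysteine set: ",
            paste(extraneous, collapse = ", "), call. = FALSE)
    lost <- intersect(lost, map$oxidative_cys)
  }
  intact <- names(map$parts)[vapply(map$parts, function(res)
    length(setdiff(res, lost)) > 0, logical(1))]
  pairs <- if (length(intact) >= 2) {
    utils::combn(sort(intact), 2, simplify = FALSE)
  } else {
    list()
  }
  structure(
    list(lost_residues = lost, intact_parts = intact,
         viable_pairs = pairs, functional = length(pairs) > 0),
    class = "failsafe_state"
  )
}

#' @export
print.failsafe_state <- function(x, ...) {
  cat("Oxidative sensor fail-safe state\n")
  cat("  lost residues:",
      if (length(x$lost_residues)) paste0("C", x$lost_residues, collapse = ", ")
      else "(none)", "\n")
  cat("  intact parts :",
      if (length(x$intact_parts)) paste(x$intact_parts, collapse = ", ")
      else "(none)", "\n")
  cat("  disulfide pairs available:",
      if (length(x$viable_pairs))
        paste(vapply(x$viable_pairs, paste, character(1), collapse = "-"),
              collapse = ", ")
      else "(none)", "\n")
  cat("  sensor", if (x$functional) "FUNCTIONAL" else "NON-FUNCTIONAL", "\n")
  invisible(x)
}

#' Predicted responsiveness to an NRF2 inducer class
#'
#' Class I inducers require Cys151; Class II requires Cys288; Class III
#' reacts with any of Cys151/273/288; Class IV (reactive oxygen species)
#' requires a functional oxidative fail-safe sensor.
#'
#' @param inducer_class one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param lost_residues integer vector of lost residue positions.
#' @param map a [keap1_sensor_map()].
#' @return `TRUE` if the response is predicted to be retained.
#' @examples
#' electrophile_response("I", c(226, 613))  # CDDO-Im response retained
#' @export
electrophile_response <- function(inducer_class = c("I", "II", "III", "IV"),
                                  lost_residues = integer(),
                                  map = keap1_sensor_map()) {
  inducer_class <- match.arg(inducer_class)
  lost <- unique(as.integer(lost_residues))
  switch(inducer_class,
    I = !(151L %in% lost),
    II = !(288L %in% lost),
    III = !all(map$electrophile_cys %in% lost),
    IV = suppressWarnings(failsafe_oxidative(lost, map))$functional
  )
}

#' Count variants by sensor category
#'
#' Applies [classify_variant()] to each variant and tabulates the
#' categories; `oxidative_affecting` sums the sensor-cysteine and
#' basic-neighbour counts.
#'
#' @param variants a list of `keap_variant` objects.
#' @param map a [keap1_sensor_map()].
#' @return an object of class `variant_counts`: a list with `counts` (named
#'   integer vector over the four categories) and `oxidative_affecting`.
#' @export
count_by_category <- function(variants, map = keap1_sensor_map()) {
  cats <- c("oxidative_sensor_cys", "oxidative_neighbor_basic",
            "electrophile_sensor_cys", "non_sensor")
  got <- vapply(variants, function(v) classify_variant(v, map)$category,
                character(1))
  counts <- vapply(cats, function(ct) sum(got == ct), integer(1))
  structure(
    list(counts = counts,
         oxidative_affecting = unname(counts[["oxidative_sensor_cys"]] +
                                        counts[["oxidative_neighbor_basic"]])),
    class = "variant_counts"
  )
}

#' @export
print.variant_counts <- function(x, ...) {
  cat("Variant counts by sensor category\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-26s %d\n", nm, x$counts[[nm]]))
  }
  cat(sprintf("  %-26s %d\n", "oxidative-affecting", x$oxidative_affecting))
  invisible(x)
}
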