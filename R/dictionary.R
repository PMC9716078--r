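#' Event and drug-class dictionary
#'
#' The event side is the acute-pancreatitis preferred-term (PT) cluster: nine
#' MedDRA-level PT strings matched case-insensitively after whitespace
#' normalization (no hierarchy traversal is attempted). The drug side maps
#' class labels to ingredient and major US brand names; matching against the
#' free-text `drugname` field is by case-insensitive substring.
#'
#' @param ap_terms character vector of event PTs (default: the nine
#'   acute-pancreatitis cluster terms).
#' @param drug_classes named list of character vectors, one per drug class.
#'   Must contain an `sglt2i` entry; each SGLT-2i generic name anchors one
#'   cohort stratum.
#' @return an object of class `event_dictionary`.
#' @export
#' @examples
#' d <- event_dictionary()
#' d$ap_terms
event_dictionary <- function(ap_terms = ap_term_cluster(),
                             drug_classes = default_drug_classes()) {
  if (length(ap_terms) == 0) {
    rlang::abort("`ap_terms` must contain at least one preferred term.",
                 class = "pvsignal_config_error")
  }
  if (!"sglt2i" %in% names(drug_classes)) {
    rlang::abort("`drug_classes` must contain an `sglt2i` entry.",
                 class = "pvsignal_config_error")
  }
  structure(
    list(ap_terms = ap_terms, drug_classes = drug_classes),
    class = "event_dictionary"
  )
}

#' @rdname event_dictionary
#' @export
ap_term_cluster <- function() {
  c(
    "Necrotizing pancreatitis",
    "Acute pancreatitis",
    "Pancreatitis",
    "Pancreatic infection",
    "Hemorrhagic necrotic pancreatitis",
    "Hemorrhagic pancreatitis",
    "Ischemic pancreatitis",
    "Pancreatic abscess",
    "Pancreatic phlegmon"
  )
}

#' @rdname event_dictionary
#' @export
default_drug_classes <- function() {
  list(
    sglt2i = c(
      "canagliflozin", "Invokana",
      "dapagliflozin", "Farxiga", "Forxiga",
      "empagliflozin", "Jardiance",
      "ertugliflozin", "Steglatro"
    ),
    dpp4i = c("sitagliptin", "Januvia", "saxagliptin", "Onglyza",
              "linagliptin", "Tradjenta", "alogliptin", "Nesina",
              "vildagliptin"),
    glp1ra = c("liraglutide", "Victoza", "exenatide", "Byetta", "Bydureon",
               "dulaglutide", "Trulicity", "semaglutide", "Ozempic",
               "lixisenatide"),
    metformin = c("metformin", "Glucophage"),
    insulin = c("insulin", "Lantus", "Humalog", "Novolog", "Levemir",
                "Tresiba"),
    glinide = c("repaglinide", "Prandin", "nateglinide", "Starlix"),
    acei = c("lisinopril", "Zestril", "Prinivil", "enalapril", "ramipril",
             "captopril", "benazepril", "perindopril", "quinapril"),
    ppi = c("omeprazole", "Prilosec", "pantoprazole", "Protonix",
            "esomeprazole", "Nexium", "lansoprazole", "Prevacid",
            "rabeprazole"),
    statin = c("atorvastatin", "Lipitor", "simvastatin", "Zocor",
               "rosuvastatin", "Crestor", "pravastatin", "lovastatin",
               "fluvastatin", "pitavastatin")
  )
}

#' SGLT-2 inhibitor generic names
#'
#' @return character vector of the four generic names, in the conventional
#'   order (canagliflozin, dapagliflozin, empagliflozin, ertugliflozin).
#' @export
sglt2i_generics <- function() {
  c("canagliflozin", "dapagliflozin", "empagliflozin", "ertugliflozin")
}

# Name patterns (ingredient + brands) for one SGLT-2i generic.
sglt2i_patterns <- function(generic) {
  brands <- list(
    canagliflozin = c("canagliflozin", "Invokana"),
    dapagliflozin = c("dapagliflozin", "Farxiga", "Forxiga"),
    empagliflozin = c("empagliflozin", "Jardiance"),
    ertugliflozin = c("ertugliflozin", "Steglatro")
  )
  brands[[generic]]
}

# TRUE where a PT string belongs to the event cluster (case/whitespace
# insensitive exact match).
is_ap_term <- function(pt, dictionary) {
  normalize_term(pt) %in% normalize_term(dictionary$ap_terms)
}

#' Write / read a dictionary as JSON
#'
#' @param dictionary an `event_dictionary`.
#' @param path file path.
#' @return `read_dictionary` returns an `event_dictionary`;
#'   `write_dictionary` returns `path` invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  jsonlite::write_json(
    list(ap_terms = dictionary$ap_terms, drug_classes = dictionary$drug_classes),
    path, auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  event_dictionary(ap_terms = x$ap_terms, drug_classes = as.list(x$drug_classes))
}
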