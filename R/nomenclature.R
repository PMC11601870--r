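# Lipid shorthand nomenclature: parsing, class vocabulary, and lipid sets.
#
# Names follow Metabolomics Workbench RefMet-style shorthand:
#   class token, then chains in "C:D" notation separated by "/" (sn-position
#   known) or "_" (unknown); "O-"/"P-" chain prefixes mark alkyl/alkenyl
#   (ether) linkage; "d"/"t" prefixes mark di-/tri-hydroxy sphingoid bases;
#   "(d7)"-style suffixes are deuterium labels on spiked internal standards;
#   "Cer C16:0" is the acyl-only ceramide shorthand (default d18:1 base).

#' Lipid class vocabulary
#'
#' Controlled vocabulary of lipid (sub)class tokens used by the parser and by
#' set construction. The vocabulary is configuration data: rows can be added
#' or dropped and the result passed to [parse_lipid_name()].
#'
#' @details `single_chain_resolved` marks classes whose names carry exactly one
#'   acyl chain (lyso-phospholipids, acylcarnitines, sterol esters, free fatty
#'   acyls): for these a single "C:D" token is a resolved chain, whereas for
#'   multi-chain classes (PC, TAG, SM, ...) it is a sum composition.
#'   Cholesteryl and sitosteryl esters are kept as separate classes (CE, SiE)
#'   to distinguish dietary plant-sterol origin from endogenous cholesterol.
#'
#' @return A data.frame with columns `class` (token), `category` (lipid
#'   category), `n_chains` (chains carried by a fully resolved name) and
#'   `single_chain_resolved` (logical, see Details).
#' @export
lipid_class_vocabulary <- function() {
  v <- rbind(
    data.frame(class = c("PC", "PE", "PS", "PG", "PI", "PA", "CL", "BMP"),
               category = "glycerophospholipid", n_chains = c(rep(2L, 6), 4L, 2L),
               single_chain_resolved = FALSE),
    data.frame(class = c("O-PC", "O-PE", "O-PS", "O-PG", "O-PI"),
               category = "ether glycerophospholipid", n_chains = 2L,
               single_chain_resolved = FALSE),
    data.frame(class = c("LPC", "LPE", "LPS", "LPG", "LPI", "LPA", "O-LPC", "O-LPE"),
               category = "lysophospholipid", n_chains = 1L,
               single_chain_resolved = TRUE),
    data.frame(class = c("TAG", "DAG", "MAG", "O-TAG"),
               category = "glycerolipid", n_chains = c(3L, 2L, 1L, 3L),
               single_chain_resolved = c(FALSE, FALSE, TRUE, FALSE)),
    data.frame(class = c("SM", "Cer", "CerP", "DCer", "HexCer", "Hex2Cer",
                         "SHexCer", "LacCer", "GM3", "SPB"),
               category = "sphingolipid",
               n_chains = c(rep(2L, 9), 1L),
               single_chain_resolved = c(rep(FALSE, 9), TRUE)),
    data.frame(class = c("Car", "FFA", "FA", "NAE", "FAHFA", "oxylipin"),
               category = "fatty acyl", n_chains = c(1L, 1L, 1L, 1L, 2L, 1L),
               single_chain_resolved = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)),
    data.frame(class = c("CE", "SiE", "Chol"),
               category = "sterol", n_chains = c(1L, 1L, 0L),
               single_chain_resolved = TRUE),
    data.frame(class = "CoQ", category = "prenol", n_chains = 0L,
               single_chain_resolved = TRUE)
  )
  rownames(v) <- NULL
  v
}

# Two-word / legacy name forms mapped onto vocabulary tokens.
.class_aliases <- c("Chol Ester" = "CE", "Cholesterol" = "Chol",
                    "cholesterol" = "Chol", "Sitosterol Ester" = "SiE",
                    "CAR" = "Car", "TG" = "TAG", "DG" = "DAG", "MG" = "MAG")

.chain_token_re <- "^(O-|P-)?(C|d|t)?([0-9]+):([0-9]+)(;O([0-9]*))?$"

.parse_chain_token <- function(tok, raw_name) {
  m <- regmatches(tok, regexec(.chain_token_re, tok))[[1]]
  if (length(m) == 0L)
    stop_parse(raw_name, tok)
  hydroxyl <- switch(m[3], d = 2L, t = 3L, 0L)
  if (nzchar(m[6]))
    hydroxyl <- hydroxyl + if (nzchar(m[7])) as.integer(m[7]) else 1L
  ch <- list(carbons = as.integer(m[4]),
             double_bonds = as.integer(m[5]),
             ether_link = if (nzchar(m[2])) sub("-$", "", m[2]) else NA_character_,
             hydroxyl_count = hydroxyl,
             sphingoid = m[3] %in% c("d", "t"),
             acyl_shorthand = identical(m[3], "C"))
  if (ch$carbons < ch$double_bonds)
    stop_parse(raw_name, tok)
  ch
}

stop_parse <- function(raw_name, token) {
  stop(structure(class = c("lipid_parse_error", "error", "condition"),
                 list(message = sprintf("cannot parse lipid name '%s': offending token '%s'",
                                        raw_name, token),
                      call = sys.call(-1), token = token, raw_name = raw_name)))
}

#' Parse a lipid shorthand name
#'
#' Deterministically parses one shorthand lipid name into a structured
#' annotation. Sum-composition names (e.g. `"PC 40:6"`, `"TAG 48:0"`,
#' `"SM d42:2"`) yield `sum_level_only = TRUE` with no chain list;
#' chain-resolved names (`"PC 18:0_22:6"`, `"PC 16:0/16:0"`) populate
#' `chains`, with `"/"` marking known sn-positions. Ether chains promote the
#' class to its `O-` form (`"PE O-18:1_22:5"` is class `O-PE`). Deuterium
#' suffixes (`"(d7)"`) are recorded as isotope labels and flag the species as
#' an internal-standard candidate. `"Cer C16:0"`-style names are the
#' acyl-only ceramide shorthand: one N-acyl chain on an (unspecified,
#' default d18:1) sphingoid base, with totals recorded acyl-only.
#'
#' @param raw_name A single nonempty lipid name string.
#' @param msi_level Annotation confidence level 1-4; level 4 (unknown) skips
#'   parsing and yields an annotation with no class.
#' @param esi_mode Optional ionization mode, `"positive"` or `"negative"`.
#' @param vocabulary Class vocabulary; see [lipid_class_vocabulary()].
#' @return An object of class `lipid_annotation`: a list with fields
#'   `raw_name`, `lipid_class`, `chains` (list of chain specs), `total_carbons`,
#'   `total_double_bonds`, `sum_level_only`, `acyl_only_totals`, `sn_known`,
#'   `isotope_label`, `is_istd`, `msi_level`, `esi_mode`.
#' @examples
#' parse_lipid_name("PC 18:0_22:6")$total_carbons   # 40
#' parse_lipid_name("PE O-18:1_22:5")$lipid_class   # "O-PE"
#' @export
parse_lipid_name <- function(raw_name, msi_level = 1L, esi_mode = NA_character_,
                             vocabulary = lipid_class_vocabulary()) {
  stopifnot(is.character(raw_name), length(raw_name) == 1L, nzchar(raw_name))
  ann <- list(raw_name = raw_name, lipid_class = NA_character_, chains = list(),
              total_carbons = NA_integer_, total_double_bonds = NA_integer_,
              sum_level_only = FALSE, acyl_only_totals = FALSE, sn_known = FALSE,
              sphingoid_sum = FALSE, isotope_label = NA_character_,
              is_istd = FALSE, msi_level = as.integer(msi_level),
              esi_mode = esi_mode)
  class(ann) <- "lipid_annotation"
  if (identical(ann$msi_level, 4L))  # unknowns carry no structural claim
    return(ann)

  nm <- trimws(raw_name)
  iso <- regmatches(nm, regexec("\\((d[0-9]+)\\)", nm))[[1]]
  if (length(iso)) {
    ann$isotope_label <- iso[2]
    ann$is_istd <- TRUE
    nm <- trimws(gsub("\\(d[0-9]+\\)", "", nm))
  }

  for (alias in names(.class_aliases))
    if (startsWith(nm, paste0(alias, " ")) || identical(nm, alias))
      nm <- sub(alias, .class_aliases[[alias]], nm, fixed = TRUE)

  cls <- sub(" .*$", "", nm)
  if (!cls %in% vocabulary$class)
    stop_parse(raw_name, cls)
  rest <- trimws(sub("^[^ ]+", "", nm))
  vrow <- vocabulary[match(cls, vocabulary$class), ]

  if (!nzchar(rest)) {  # backbone-only species (Chol, CoQ)
    if (vrow$n_chains != 0L) stop_parse(raw_name, "<missing chains>")
    ann$lipid_class <- cls
    ann$total_carbons <- 0L
    ann$total_double_bonds <- 0L
    return(ann)
  }

  ann$sn_known <- grepl("/", rest, fixed = TRUE)
  # protect ether prefixes, then split on the chain separators ("/" sn-known,
  # "_" unknown, dashes in internal-standard names)
  prot <- gsub("O-", "O\u01", gsub("P-", "P\u01", rest), fixed = TRUE)
  toks <- strsplit(prot, "[/_–-]")[[1]]
  toks <- gsub("\u01", "-", toks, fixed = TRUE)
  toks <- trimws(toks[nzchar(trimws(toks))])
  chains <- lapply(toks, .parse_chain_token, raw_name = raw_name)

  single_sum <- length(chains) == 1L && !vrow$single_chain_resolved &&
    !chains[[1]]$acyl_shorthand
  if (single_sum) {
    ann$sum_level_only <- TRUE
    ann$sphingoid_sum <- chains[[1]]$sphingoid
    ann$total_carbons <- chains[[1]]$carbons
    ann$total_double_bonds <- chains[[1]]$double_bonds
  } else {
    ann$chains <- chains
    ann$acyl_only_totals <- length(chains) == 1L && chains[[1]]$acyl_shorthand
    ann$total_carbons <- sum(vapply(chains, `[[`, 0L, "carbons"))
    ann$total_double_bonds <- sum(vapply(chains, `[[`, 0L, "double_bonds"))
  }

  ether <- any(vapply(chains, function(ch) !is.na(ch$ether_link), FALSE))
  if (ether && vrow$category == "glycerophospholipid")
    cls <- paste0("O-", cls)
  ann$lipid_class <- cls
  ann
}

#' @export
print.lipid_annotation <- function(x, ...) {
  cat(sprintf("<lipid_annotation> %s  class=%s  %d:%d%s  MSI %s\n",
              x$raw_name, x$lipid_class, x$total_carbons, x$total_double_bonds,
              if (x$sum_level_only) " (sum level)" else "", x$msi_level))
  invisible(x)
}

#' Write a parsed annotation back to shorthand text
#'
#' Inverse of [parse_lipid_name()] for chain-resolved and sum-level
#' annotations; re-parsing the result yields an identical structure.
#'
#' @param ann A `lipid_annotation`.
#' @return A single name string.
#' @export
format_lipid_name <- function(ann) {
  stopifnot(inherits(ann, "lipid_annotation"))
  base_class <- sub("^O-", "", ann$lipid_class)
  has_ether <- length(ann$chains) &&
    any(vapply(ann$chains, function(ch) !is.na(ch$ether_link), FALSE))
  cls_out <- if (startsWith(ann$lipid_class, "O-") && has_ether) base_class else ann$lipid_class
  iso <- if (!is.na(ann$isotope_label)) sprintf("(%s)", ann$isotope_label) else ""
  if (ann$sum_level_only || length(ann$chains) == 0L) {
    if (is.na(ann$total_carbons)) return(ann$raw_name)
    if (ann$total_carbons == 0L && length(ann$chains) == 0L && !ann$sum_level_only)
      return(paste0(cls_out, iso))
    pre <- if (ann$sphingoid_sum) "d" else ""
    return(sprintf("%s %s%d:%d%s", cls_out, pre, ann$total_carbons,
                   ann$total_double_bonds, iso))
  }
  fmt1 <- function(ch) {
    pre <- if (!is.na(ch$ether_link)) paste0(ch$ether_link, "-") else ""
    base <- if (ch$sphingoid) switch(as.character(ch$hydroxyl_count),
                                     "2" = "d", "3" = "t", "d")
            else if (ch$acyl_shorthand) "C" else ""
    sprintf("%s%s%d:%d", pre, base, ch$carbons, ch$double_bonds)
  }
  sep <- if (ann$sn_known) "/" else "_"
  sprintf("%s %s%s", cls_out, paste(vapply(ann$chains, fmt1, ""), collapse = sep), iso)
}

#' Parse an annotation table
#'
#' Vectorized front-end to [parse_lipid_name()]: takes a feature table
#' (feature_id, name, msi_level, esi_mode) and returns a flat annotation
#' data.frame with the parsed chains kept as a list-column.
#'
#' @param features data.frame with columns `feature_id`, `name`, `msi_level`,
#'   and optionally `esi_mode`.
#' @param vocabulary See [lipid_class_vocabulary()].
#' @return data.frame with one row per feature: `feature_id`, `name`,
#'   `lipid_class`, `total_carbons`, `total_double_bonds`, `sum_level_only`,
#'   `acyl_only_totals`, `is_istd`, `isotope_label`, `msi_level`, `esi_mode`,
#'   plus list-column `chains`.
#' @export
parse_lipid_annotations <- function(features, vocabulary = lipid_class_vocabulary()) {
  stopifnot(is.data.frame(features), all(c("feature_id", "name", "msi_level") %in% names(features)))
  esi <- if ("esi_mode" %in% names(features)) features$esi_mode else NA_character_
  anns <- mapply(parse_lipid_name, features$name, features$msi_level,
                 esi, MoreArgs = list(vocabulary = vocabulary), SIMPLIFY = FALSE)
  out <- data.frame(
    feature_id = features$feature_id,
    name = features$name,
    lipid_class = vapply(anns, `[[`, "", "lipid_class"),
    total_carbons = vapply(anns, `[[`, 0L, "total_carbons"),
    total_double_bonds = vapply(anns, `[[`, 0L, "total_double_bonds"),
    sum_level_only = vapply(anns, `[[`, FALSE, "sum_level_only"),
    acyl_only_totals = vapply(anns, `[[`, FALSE, "acyl_only_totals"),
    is_istd = vapply(anns, `[[`, FALSE, "is_istd"),
    isotope_label = vapply(anns, `[[`, "", "isotope_label"),
    msi_level = as.integer(features$msi_level),
    esi_mode = if (length(esi) == 1L) rep(esi, nrow(features)) else esi,
    stringsAsFactors = FALSE)
  out$chains <- lapply(anns, `[[`, "chains")
  rownames(out) <- NULL
  out
}

#' Read / write annotation tables (TSV)
#'
#' @param path TSV with columns feature_id, name, msi_level, esi_mode.
#' @return `read_annotation_table`: parsed annotation data.frame
#'   (see [parse_lipid_annotations()]).
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  parse_lipid_annotations(tab)
}

#' @rdname read_annotation_table
#' @param annotations Annotation data.frame.
#' @export
write_annotation_table <- function(annotations, path) {
  keep <- c("feature_id", "name", "msi_level", "esi_mode")
  utils::write.table(annotations[, keep], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build lipid-class sets
#'
#' One set per lipid class with at least `min_size` members; unknowns
#' (MSI level 4) are excluded before counting.
#'
#' @param annotations Annotation data.frame from [parse_lipid_annotations()].
#' @param min_size Minimal set size (default 10).
#' @return A `lipid_set_catalog`: list with `sets` (named list of feature-id
#'   vectors) and `set_kind = "class"`.
#' @export
build_class_sets <- function(annotations, min_size = 10L) {
  stopifnot(is.data.frame(annotations), min_size >= 1L)
  if (nrow(annotations) == 0L) stop("empty annotation list")
  ok <- annotations$msi_level <= 3L & !is.na(annotations$lipid_class)
  sets <- split(annotations$feature_id[ok], annotations$lipid_class[ok])
  sets <- sets[lengths(sets) >= min_size]
  structure(list(sets = sets, set_kind = "class"), class = "lipid_set_catalog")
}

#' Export a set catalog as JSON
#' @param catalog A `lipid_set_catalog`.
#' @param path Output file.
#' @export
write_set_catalog <- function(catalog, path) {
  jsonlite::write_json(catalog$sets, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Triacylglycerol saturation and chain-length categories
#'
#' Bins TAG species by total double bonds (0 saturated, 1 monounsaturated,
#' >= 2 polyunsaturated) and total carbons: short-chain C30-48, medium-chain
#' C49-52, long-chain C53-55, very-long-chain C56-60; totals outside 30-60
#' are flagged `"other"`.
#'
#' @param total_carbons,total_double_bonds Integer vectors (TAG totals).
#' @return data.frame with `saturation`, `chain_length` and logical `flagged`.
#' @export
assign_tag_category <- function(total_carbons, total_double_bonds) {
  stopifnot(length(total_carbons) == length(total_double_bonds))
  sat <- ifelse(total_double_bonds == 0L, "saturated",
         ifelse(total_double_bonds == 1L, "monounsaturated", "polyunsaturated"))
  len <- cut(total_carbons, breaks = c(29.5, 48.5, 52.5, 55.5, 60.5),
             labels = c("short-chain", "medium-chain", "long-chain",
                        "very-long-chain"))
  len <- as.character(len)
  flagged <- is.na(len)
  len[flagged] <- "other"
  data.frame(saturation = sat, chain_length = len, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Select PUFA-containing phospholipid species
#'
#' Selects chain-resolved species in the given classes whose chain multiset
#' holds one anchor chain (default 16:0, 16:1, 18:0 or 18:1) together with one
#' target PUFA chain (default 20:4 arachidonic or 22:6 docosahexaenoic);
#' the basis of the per-class DHA:ARA ratio. Sum-level species in the target
#' classes cannot be assessed and are reported as skipped.
#'
#' @param annotations Annotation data.frame with `chains` list-column.
#' @param classes Lipid classes to search (default `c("PC", "PE")`).
#' @param target_chains PUFA chains, `"C:D"` strings.
#' @param anchor_chains Anchor chains, `"C:D"` strings.
#' @return data.frame (`feature_id`, `lipid_class`, `target`) with attribute
#'   `"skipped"` listing sum-level feature ids in `classes`.
#' @export
select_pufa_species <- function(annotations, classes = c("PC", "PE"),
                                target_chains = c("20:4", "22:6"),
                                anchor_chains = c("16:0", "16:1", "18:0", "18:1")) {
  in_cls <- annotations$lipid_class %in% classes
  skipped <- annotations$feature_id[in_cls &
    (annotations$sum_level_only | lengths(annotations$chains) < 2L)]
  rows <- which(in_cls & !annotations$sum_level_only & lengths(annotations$chains) >= 2L)
  hits <- list()
  for (i in rows) {
    chs <- annotations$chains[[i]]
    # ether chains are not plain acyl anchors/targets
    key <- vapply(chs, function(ch)
      if (is.na(ch$ether_link)) sprintf("%d:%d", ch$carbons, ch$double_bonds)
      else NA_character_, "")
    for (tg in target_chains) {
      ti <- which(key == tg)
      if (length(ti) && any(key[-ti[1]] %in% anchor_chains))
        hits[[length(hits) + 1L]] <- data.frame(
          feature_id = annotations$feature_id[i],
          lipid_class = annotations$lipid_class[i],
          target = tg, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits)
         else data.frame(feature_id = character(), lipid_class = character(),
                         target = character(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}
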