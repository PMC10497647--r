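#' Construct an evidence knowledgebase
#'
#' The knowledgebase is the queryable store of parameterized evidence that the
#' scoring engine consumes: a gene table (with aliases), a compound table
#' (registered vs. developmental, with approved indications), and a list of
#' evidence items linking an alteration or gene to its oncogenicity, a
#' molecular target, or a compound, in a given tumor-type context.
#'
#' @param genes data.frame with columns `symbol` and `aliases`
#'   (comma-separated string, may be empty).
#' @param compounds data.frame with columns `id`, `name`, `registered`
#'   (logical) and `approved_indications` (comma-separated tumor-type codes,
#'   empty for developmental compounds).
#' @param evidence data.frame with columns `id`, `subject_gene`,
#'   `subject_alteration` (`NA` for gene-level evidence), `object_kind`
#'   (`"oncogenicity"`, `"target"` or `"compound"`), `object_id` (`NA` for
#'   oncogenicity), `direction` (+1 sensitivity/driver-supporting, -1
#'   resistance/negative), `evidence_class`, `tumor_type` (`NA` =
#'   tumor-type-agnostic), `base_reliability` (`NA` = use the class default
#'   from [scoring_params()]), `source_ref`.
#' @param version free-text version string.
#' @param tumor_types character vector: the controlled tumor-type vocabulary.
#' @return An object of class `dda_kb`.
#' @seealso [load_knowledgebase()], [query_evidence()], [registered_compounds()]
#' @export
knowledgebase <- function(genes, compounds, evidence, version = "0",
                          tumor_types = character()) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  compounds <- as.data.frame(compounds, stringsAsFactors = FALSE)
  evidence <- as.data.frame(evidence, stringsAsFactors = FALSE)
  kb <- structure(
    list(genes = genes, compounds = compounds, evidence = evidence,
         version = as.character(version),
         tumor_types = as.character(tumor_types)),
    class = "dda_kb")
  validate_knowledgebase(kb)
}

empty_evidence <- function() {
  data.frame(id = character(), subject_gene = character(),
             subject_alteration = character(), object_kind = character(),
             object_id = character(), direction = integer(),
             evidence_class = character(), tumor_type = character(),
             base_reliability = numeric(), source_ref = character(),
             stringsAsFactors = FALSE)
}

empty_compounds <- function() {
  data.frame(id = character(), name = character(), registered = logical(),
             approved_indications = character(), stringsAsFactors = FALSE)
}

split_csv_field <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Validate a knowledgebase and build its alias index
#'
#' Checks referential integrity (every evidence subject resolves to a gene,
#' every compound reference resolves, every tumor type is in the vocabulary),
#' uniqueness of compound ids, and alias/symbol collisions. Gene matching is
#' case-insensitive, so an alias colliding with another gene's symbol or alias
#' is a load-time error: silent mis-mapping would corrupt every downstream
#' score.
#'
#' @param kb a `dda_kb` object.
#' @return The validated knowledgebase with its `alias_map` attribute set.
#' @export
validate_knowledgebase <- function(kb) {
  g <- kb$genes; cp <- kb$compounds; ev <- kb$evidence
  if (nrow(g) == 0 || any(!nzchar(g$symbol)) || anyNA(g$symbol))
    stop("knowledgebase validation: empty or missing gene symbol")
  if (anyDuplicated(toupper(g$symbol)))
    stop("knowledgebase validation: duplicate gene symbols")
  # alias map: lowercased alias/symbol -> canonical symbol
  map <- stats::setNames(g$symbol, tolower(g$symbol))
  for (i in seq_len(nrow(g))) {
    al <- split_csv_field(if ("aliases" %in% names(g)) g$aliases[i] else "")
    for (a in tolower(al)) {
      if (a %in% names(map) && map[[a]] != g$symbol[i])
        stop(sprintf("knowledgebase validation: ambiguous alias '%s' (maps to %s and %s)",
                     a, map[[a]], g$symbol[i]))
      map[[a]] <- g$symbol[i]
    }
  }
  if (nrow(cp) > 0 && anyDuplicated(cp$id))
    stop("knowledgebase validation: duplicate compound ids")
  if (nrow(cp) > 0) {
    bad <- !cp$registered & nzchar(ifelse(is.na(cp$approved_indications), "", cp$approved_indications))
    if (any(bad))
      stop(sprintf("knowledgebase validation: developmental compound(s) with approved indications: %s",
                   paste(cp$id[bad], collapse = ", ")))
  }
  if (nrow(ev) > 0) {
    if (any(!ev$direction %in% c(-1L, 1L)))
      stop("knowledgebase validation: direction must be +1 or -1")
    if (any(!ev$evidence_class %in% EVIDENCE_CLASSES))
      stop(sprintf("knowledgebase validation: unknown evidence_class in item(s) %s",
                   paste(ev$id[!ev$evidence_class %in% EVIDENCE_CLASSES], collapse = ", ")))
    if (any(!ev$object_kind %in% OBJECT_KINDS))
      stop("knowledgebase validation: unknown object_kind")
    br <- ev$base_reliability
    if (any(!is.na(br) & br <= 0))
      stop("knowledgebase validation: base_reliability must be > 0")
    unresolved <- !(tolower(ev$subject_gene) %in% names(map))
    if (any(unresolved))
      stop(sprintf("knowledgebase validation: evidence with unknown subject gene: %s",
                   paste(ev$id[unresolved], collapse = ", ")))
    is_cpd <- ev$object_kind == "compound"
    dangling <- is_cpd & !(ev$object_id %in% cp$id)
    if (any(dangling))
      stop(sprintf("knowledgebase validation: evidence referencing unknown compound: %s",
                   paste(ev$id[dangling], collapse = ", ")))
    tt <- ev$tumor_type[!is.na(ev$tumor_type)]
    if (length(tt) && any(!tt %in% kb$tumor_types))
      stop(sprintf("knowledgebase validation: tumor type(s) outside vocabulary: %s",
                   paste(unique(tt[!tt %in% kb$tumor_types]), collapse = ", ")))
  }
  attr(kb, "alias_map") <- map
  kb
}

#' Resolve a gene symbol or alias to its canonical symbol
#'
#' @param kb a `dda_kb`.
#' @param symbol gene symbol or alias; matching is case-insensitive.
#' @return The canonical symbol, or `NA_character_` if unknown.
#' @export
resolve_gene <- function(kb, symbol) {
  map <- attr(kb, "alias_map")
  hit <- map[tolower(symbol)]
  unname(ifelse(is.na(names(hit)) | is.na(hit), NA_character_, hit))
}

#' Read a knowledgebase from its sectioned text serialization
#'
#' The on-disk format is a single UTF-8 text file with `[meta]`,
#' `[tumor_types]`, `[genes]`, `[compounds]` and `[evidence]` sections; each
#' section body is tab-separated with a header row (except `[tumor_types]`,
#' one code per line). Chosen for diffability and hand-editable fixtures.
#' Empty strings in nullable columns read back as `NA`.
#'
#' @param path file path.
#' @return A validated `dda_kb`.
#' @export
load_knowledgebase <- function(path) {
  if (!file.exists(path)) stop("knowledgebase file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  sec_idx <- grep("^\\[[a-z_]+\\]$", lines)
  if (!length(sec_idx)) stop("knowledgebase parse error: no sections found in ", path)
  sections <- list()
  for (k in seq_along(sec_idx)) {
    nm <- gsub("\\[|\\]", "", lines[sec_idx[k]])
    from <- sec_idx[k] + 1L
    to <- if (k < length(sec_idx)) sec_idx[k + 1L] - 1L else length(lines)
    body <- lines[seq_len(max(0L, to - from + 1L)) + from - 1L]
    sections[[nm]] <- body[nzchar(body)]
  }
  read_tsv_block <- function(body) {
    if (length(body) < 1) stop("knowledgebase parse error: empty section")
    utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                      stringsAsFactors = FALSE, na.strings = "", quote = "")
  }
  meta <- read_tsv_block(sections$meta %||% c("version", "0"))
  version <- as.character(meta$version[1] %||% "0")
  tumor_types <- sections$tumor_types %||% character()
  genes <- read_tsv_block(sections$genes)
  genes$aliases <- ifelse(is.na(genes$aliases), "", genes$aliases)
  compounds <- if (is.null(sections$compounds)) empty_compounds() else
    read_tsv_block(sections$compounds)
  if (nrow(compounds)) {
    compounds$registered <- as.logical(compounds$registered)
    compounds$approved_indications <-
      ifelse(is.na(compounds$approved_indications), "", compounds$approved_indications)
  }
  evidence <- if (is.null(sections$evidence)) empty_evidence() else
    read_tsv_block(sections$evidence)
  if (nrow(evidence)) {
    evidence$direction <- as.integer(evidence$direction)
    evidence$base_reliability <- as.numeric(evidence$base_reliability)
    for (col in c("subject_alteration", "object_id", "tumor_type", "source_ref"))
      evidence[[col]] <- as.character(evidence[[col]])
    evidence$id <- as.character(evidence$id)
  }
  knowledgebase(genes, compounds, evidence, version = version,
                tumor_types = tumor_types)
}

#' Write a knowledgebase to its sectioned text serialization
#'
#' Inverse of [load_knowledgebase()]; a load/write round trip preserves every
#' field exactly.
#'
#' @param kb a `dda_kb`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_knowledgebase <- function(kb, path) {
  fmt_block <- function(df) {
    df <- as.data.frame(lapply(df, function(x) {
      x <- as.character(x)
      ifelse(is.na(x), "", x)
    }), stringsAsFactors = FALSE)
    c(paste(names(df), collapse = "\t"),
      if (nrow(df)) do.call(paste, c(unname(df), sep = "\t")))
  }
  ev <- kb$evidence
  if (nrow(ev)) ev$direction <- sprintf("%+d", ev$direction)
  out <- c(
    "# oncodda knowledgebase",
    "[meta]", "version", kb$version,
    "[tumor_types]", kb$tumor_types,
    "[genes]", fmt_block(kb$genes),
    "[compounds]", fmt_block(kb$compounds),
    "[evidence]", fmt_block(ev))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Query evidence for a gene/alteration in a case context
#'
#' Returns every evidence item whose subject gene matches (directly or via
#' alias) and whose subject alteration is either `NA` (gene-level evidence)
#' or equal to the queried alteration. Each returned row is annotated with
#' the match flags the scoring engine weights on: `exact_match` (the item is
#' about this very alteration, not just the gene) and `same_tumor` (the
#' item's tumor-type context equals the case's).
#'
#' @param kb a `dda_kb`.
#' @param gene gene symbol or alias.
#' @param alteration alteration descriptor, or `NULL`/`NA` to query
#'   gene-level evidence only.
#' @param tumor_type the case's tumor-type code (used only to set
#'   `same_tumor`).
#' @return The matching subset of `kb$evidence` with `exact_match` and
#'   `same_tumor` logical columns appended. Unknown genes yield an empty
#'   result with a warning (unprofiled genes are legal input).
#' @export
query_evidence <- function(kb, gene, alteration = NULL, tumor_type = NULL) {
  sym <- resolve_gene(kb, gene)
  ev <- kb$evidence
  if (is.na(sym)) {
    warning("query_evidence: unknown gene '", gene, "'")
    ev <- ev[0, , drop = FALSE]
  } else {
    alt <- if (is.null(alteration) || is.na(alteration)) NA_character_ else as.character(alteration)
    keep <- ev$subject_gene == sym &
      (is.na(ev$subject_alteration) |
         (!is.na(alt) & ev$subject_alteration == alt))
    ev <- ev[keep, , drop = FALSE]
  }
  ev$exact_match <- !is.na(ev$subject_alteration)
  ev$same_tumor <- if (is.null(tumor_type)) rep(FALSE, nrow(ev)) else
    !is.na(ev$tumor_type) & ev$tumor_type == tumor_type
  rownames(ev) <- NULL
  ev
}

#' Ids of registered compounds
#'
#' Registered means approved on- or off-label somewhere; developmental
#' compounds are excluded, matching the actionability definition used
#' throughout the package.
#'
#' @param kb a `dda_kb`.
#' @return Character vector of compound ids.
#' @export
registered_compounds <- function(kb) {
  kb$compounds$id[kb$compounds$registered]
}

#' Knowledgebase summary statistics
#'
#' @param kb a `dda_kb`.
#' @return Named list with entity counts and per-class evidence tallies.
#' @export
kb_stats <- function(kb) {
  list(
    n_genes = nrow(kb$genes),
    n_compounds = nrow(kb$compounds),
    n_registered = sum(kb$compounds$registered),
    n_evidence = nrow(kb$evidence),
    n_negative = sum(kb$evidence$direction == -1L),
    by_class = table(factor(kb$evidence$evidence_class, levels = EVIDENCE_CLASSES)),
    version = kb$version)
}

#' @export
print.dda_kb <- function(x, ...) {
  s <- kb_stats(x)
  cat(sprintf("<dda_kb v%s> %d genes, %d compounds (%d registered), %d evidence items (%d negative)\n",
              s$version, s$n_genes, s$n_compounds, s$n_registered,
              s$n_evidence, s$n_negative))
  invisible(x)
}
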