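# Literature-mined mutation-disease evidence: loading, variant queries,
# two-level summaries and trigger-word highlighting. Relation records are
# consumed from upstream text-mining output; no mining happens here.

.RSID_RE <- "^rs[0-9]+$"
.POSKEY_RE <- "^(chr)?([0-9]+|X|Y|M|MT):[0-9]+:[ACGTN]+:[ACGTN]+$"

.is_valid_kb_key <- function(x) {
  grepl(.RSID_RE, x) | grepl(.POSKEY_RE, x, ignore.case = FALSE)
}

.normalize_kb_key <- function(x) {
  pos <- grepl(.POSKEY_RE, x)
  parts <- strsplit(x[pos], ":", fixed = TRUE)
  x[pos] <- vapply(parts, function(p)
    variant_key(p[1], p[2], p[3], p[4]), character(1))
  x
}

#' Load a mutation-disease relations table into a knowledge base
#'
#' Required columns: `variant_id` (RSID or `chrom:pos:ref:alt`),
#' `disease_id`, `disease_category`, `pmid`, `sentence`; optional: `trigger`,
#' `dependency_path`. Invalid rows (bad key shape, `pmid <= 0`, empty
#' sentence) are rejected with a warning naming their line numbers; exact
#' duplicates on (variant_id, disease_id, pmid, sentence) are dropped.
#'
#' @param path Path to the relations TSV (or a `data.frame`).
#' @param alias Optional alias table (TSV path or `data.frame`) with columns
#'   `rsid`, `key` mapping RSIDs to positional keys.
#' @return A `knowledge_base` object.
#' @export
load_relations <- function(path, alias = NULL) {
  rel <- if (is.character(path)) read.delim(path, stringsAsFactors = FALSE)
         else path
  required <- c("variant_id", "disease_id", "disease_category", "pmid",
                "sentence")
  missing_cols <- setdiff(required, names(rel))
  if (length(missing_cols))
    stop("relations schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (opt in c("trigger", "dependency_path"))
    if (!opt %in% names(rel)) rel[[opt]] <- rep(NA_character_, nrow(rel))
  rel$pmid <- suppressWarnings(as.integer(rel$pmid))

  ok <- !is.na(rel$pmid) & rel$pmid > 0 &
    !is.na(rel$sentence) & nzchar(rel$sentence) &
    .is_valid_kb_key(rel$variant_id)
  if (any(!ok)) {
    # +1 header line so numbers refer to the file
    warning("rejected relation row(s) at line(s): ",
            paste(which(!ok) + 1L, collapse = ", "))
    rel <- rel[ok, , drop = FALSE]
  }
  rel$variant_id <- .normalize_kb_key(rel$variant_id)
  dup <- duplicated(rel[, c("variant_id", "disease_id", "pmid", "sentence")])
  rel <- rel[!dup, , drop = FALSE]
  rownames(rel) <- NULL

  alias_df <- NULL
  if (!is.null(alias)) {
    alias_df <- if (is.character(alias)) read.delim(alias, stringsAsFactors = FALSE)
                else alias
    stopifnot(all(c("rsid", "key") %in% names(alias_df)))
    alias_df$key <- .normalize_kb_key(alias_df$key)
  }
  structure(list(relations = rel, alias = alias_df),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("knowledge base:", nrow(x$relations), "relations,",
      length(unique(x$relations$variant_id)), "variants\n")
  invisible(x)
}

# All keys equivalent to `key` under the alias table (including itself).
.expand_key <- function(kb, key) {
  keys <- key
  if (!is.null(kb$alias)) {
    keys <- union(keys, kb$alias$key[kb$alias$rsid %in% keys])
    keys <- union(keys, kb$alias$rsid[kb$alias$key %in% keys])
  }
  keys
}

#' Query evidence relations for one variant
#'
#' Accepts an RSID or a `chrom:pos:ref:alt` key; if an alias table was
#' loaded, both spellings of the same variant return identical results.
#' Relations are ordered by (disease_category, disease_id, pmid). Unknown
#' variants return an empty set.
#'
#' @param kb A [load_relations()] knowledge base.
#' @param key RSID or positional variant key.
#' @return `data.frame` of matching relations.
#' @export
query_variant <- function(kb, key) {
  stopifnot(length(key) == 1)
  if (!.is_valid_kb_key(key))
    stop("malformed variant key: '", key, "'")
  keys <- .expand_key(kb, .normalize_kb_key(key))
  hits <- kb$relations[kb$relations$variant_id %in% keys, , drop = FALSE]
  hits <- hits[order(hits$disease_category, hits$disease_id, hits$pmid), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Count knowledge-base relations per variant key (vectorized)
#'
#' @param kb A knowledge base.
#' @param keys Character vector of positional keys or RSIDs.
#' @return Integer vector of relation counts.
#' @export
kb_count <- function(kb, keys) {
  tab <- table(kb$relations$variant_id)
  counts <- as.integer(tab[keys])
  counts[is.na(counts)] <- 0L
  if (!is.null(kb$alias)) {
    # add counts recorded under the aliased spelling
    other <- rep(NA_character_, length(keys))
    i <- match(keys, kb$alias$rsid); other[!is.na(i)] <- kb$alias$key[i[!is.na(i)]]
    j <- match(keys, kb$alias$key); other[!is.na(j)] <- kb$alias$rsid[j[!is.na(j)]]
    extra <- as.integer(tab[other])
    extra[is.na(extra)] <- 0L
    counts <- counts + extra
  }
  counts
}

#' Two-level evidence summary (category -> disease -> count)
#'
#' Inner disease counts sum to their category count; category counts sum to
#' the total number of relations.
#'
#' @param relations `data.frame` of relations (as from [query_variant()]).
#' @return A `kb_summary` list: `total`, and `categories` mapping each
#'   category to `list(n =, diseases = named counts)`.
#' @export
summarize_two_level <- function(relations) {
  out <- list(total = nrow(relations), categories = list())
  if (nrow(relations)) {
    for (cat in sort(unique(relations$disease_category))) {
      sub <- relations[relations$disease_category == cat, , drop = FALSE]
      dis <- table(sub$disease_id)
      out$categories[[cat]] <- list(
        n = nrow(sub),
        diseases = stats::setNames(as.integer(dis), names(dis)))
    }
  }
  structure(out, class = "kb_summary")
}

#' Mark the trigger word in an evidence sentence
#'
#' The first case-insensitive occurrence of the trigger is wrapped in
#' `**`...`**`; sentences without a usable trigger are returned unchanged.
#'
#' @param sentence Sentence text (or a one-row relation `data.frame`).
#' @param trigger Trigger word; taken from the relation when omitted.
#' @return The sentence with the trigger span marked.
#' @export
highlight_sentence <- function(sentence, trigger = NULL) {
  if (is.data.frame(sentence)) {
    trigger <- sentence$trigger[1]
    sentence <- sentence$sentence[1]
  }
  if (is.null(trigger) || is.na(trigger) || !nzchar(trigger)) return(sentence)
  pat <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", trigger)  # literal match
  m <- regexpr(pat, sentence, ignore.case = TRUE)
  if (m == -1L) return(sentence)
  span <- substr(sentence, m, m + attr(m, "match.length") - 1L)
  paste0(substr(sentence, 1, m - 1L), "**", span, "**",
         substr(sentence, m + attr(m, "match.length"), nchar(sentence)))
}
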