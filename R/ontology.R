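#' Ontology DAG
#'
#' An `ontology_dag` holds Gene Ontology style terms and their directed
#' child-to-parent relations (`is_a`, optionally `part_of`). The relation
#' graph must be acyclic; obsolete terms are retained but flagged and carry
#' no parent edges.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`,
#'   `obsolete` (logical).
#' @param parents data.frame with columns `child`, `parent`, `relation`.
#' @return An object of class `ontology_dag`.
#' @export
ontology_dag <- function(terms, parents) {
  stopifnot(all(c("id", "name", "namespace", "obsolete") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(parents)))
  terms <- terms[!duplicated(terms$id), , drop = FALSE]
  rownames(terms) <- NULL
  parents <- unique(parents[, c("child", "parent", "relation")])
  unknown <- setdiff(c(parents$child, parents$parent), terms$id)
  if (length(unknown) > 0) {
    stop("parent edges reference unknown terms: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  dag <- structure(list(terms = terms, parents = parents),
                   class = "ontology_dag")
  if (nrow(parents) > 0) {
    g <- igraph::graph_from_data_frame(parents[, c("child", "parent")],
                                       directed = TRUE)
    if (!igraph::is_dag(g)) stop("cyclic parent relations in ontology")
  }
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", nrow(x$terms), "terms (",
      sum(x$terms$obsolete), "obsolete ),",
      nrow(x$parents), "parent edges\n")
  invisible(x)
}

#' Parse an OBO 1.2/1.4 ontology file
#'
#' Reads `[Term]` stanzas; keeps `is_a` and `relationship: part_of` parent
#' edges. Obsolete terms are retained with their flag set but contribute no
#' parent edges.
#'
#' @param path path to an OBO file.
#' @return An [ontology_dag()].
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush_term <- function(cur) {
    if (is.null(cur) || is.null(cur$id)) return(NULL)
    cur
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "") next
    if (startsWith(line, "[")) {
      if (in_term && !is.null(cur)) terms[[length(terms) + 1L]] <- cur
      in_term <- identical(line, "[Term]")
      cur <- if (in_term) list(parents = character(), relations = character(),
                               obsolete = FALSE) else NULL
      next
    }
    if (!in_term) next
    colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 1) stop("malformed OBO stanza line ", i, ": ", line)
    key <- substr(line, 1, colon - 1L)
    val <- trimws(substr(line, colon + 1L, nchar(line)))
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "is_a") {
      target <- trimws(sub("!.*$", "", val))
      if (!grepl("^\\S+$", target)) stop("malformed is_a at line ", i, ": ", line)
      cur$parents <- c(cur$parents, target)
      cur$relations <- c(cur$relations, "is_a")
    } else if (key == "relationship") {
      parts <- strsplit(trimws(sub("!.*$", "", val)), "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        cur$parents <- c(cur$parents, parts[2])
        cur$relations <- c(cur$relations, "part_of")
      }
    }
  }
  if (in_term && !is.null(cur)) terms[[length(terms) + 1L]] <- cur
  if (length(terms) == 0) stop("no [Term] stanzas found in ", path)
  tdf <- data.frame(
    id = vapply(terms, function(t) t$id %||% NA_character_, character(1)),
    name = vapply(terms, function(t) t$name %||% "", character(1)),
    namespace = vapply(terms, function(t) t$namespace %||% "", character(1)),
    obsolete = vapply(terms, function(t) isTRUE(t$obsolete), logical(1)),
    stringsAsFactors = FALSE
  )
  if (anyNA(tdf$id)) stop("OBO [Term] stanza without id")
  plist <- lapply(terms, function(t) {
    if (isTRUE(t$obsolete) || length(t$parents) == 0) return(NULL)
    data.frame(child = t$id, parent = t$parents, relation = t$relations,
               stringsAsFactors = FALSE)
  })
  pdf <- do.call(rbind, plist)
  if (is.null(pdf)) {
    pdf <- data.frame(child = character(), parent = character(),
                      relation = character(), stringsAsFactors = FALSE)
  }
  ontology_dag(tdf, pdf)
}

#' Write an ontology to OBO format
#'
#' @param dag an [ontology_dag()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  ord <- radix_order(dag$terms$id)
  for (i in ord) {
    t <- dag$terms[i, ]
    out <- c("[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (nzchar(t$namespace)) out <- c(out, paste0("namespace: ", t$namespace))
    if (t$obsolete) out <- c(out, "is_obsolete: true")
    pe <- dag$parents[dag$parents$child == t$id, , drop = FALSE]
    if (nrow(pe) > 0) {
      pe <- pe[radix_order(pe$relation, pe$parent), , drop = FALSE]
      for (j in seq_len(nrow(pe))) {
        out <- c(out, if (pe$relation[j] == "is_a") {
          paste0("is_a: ", pe$parent[j])
        } else {
          paste0("relationship: ", pe$relation[j], " ", pe$parent[j])
        })
      }
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

# Named list: term id -> character vector of proper ancestors under the
# chosen relations. Memoized over a topological order.
ancestor_table <- function(dag, relations = c("is_a", "part_of")) {
  pe <- dag$parents[dag$parents$relation %in% relations, , drop = FALSE]
  ids <- dag$terms$id
  anc <- stats::setNames(vector("list", length(ids)), ids)
  if (nrow(pe) == 0) return(lapply(anc, function(x) character()))
  g <- igraph::graph_from_data_frame(pe[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = ids))
  topo <- names(igraph::topo_sort(g, mode = "in"))
  parents_of <- split(pe$parent, pe$child)
  for (id in topo) {
    ps <- parents_of[[id]]
    if (is.null(ps)) {
      anc[[id]] <- character()
    } else {
      anc[[id]] <- radix_sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
    }
  }
  anc
}

#' Ancestors of a term
#'
#' Proper ancestors (excluding the term itself) reachable through the chosen
#' relation types.
#'
#' @param dag an [ontology_dag()].
#' @param term a term id.
#' @param relations relation types to traverse.
#' @return Character vector of ancestor term ids.
#' @export
term_ancestors <- function(dag, term, relations = c("is_a", "part_of")) {
  stopifnot(term %in% dag$terms$id)
  seen <- character()
  frontier <- term
  pe <- dag$parents[dag$parents$relation %in% relations, , drop = FALSE]
  while (length(frontier) > 0) {
    ps <- unique(pe$parent[pe$child %in% frontier])
    ps <- setdiff(ps, seen)
    seen <- c(seen, ps)
    frontier <- ps
  }
  radix_sort(seen)
}

#' Namespace roots of an ontology
#'
#' Non-obsolete terms with no parent under the traversed relations. These are
#' excluded from inferred annotations: every protein would otherwise be
#' annotated to them, which destroys ranking specificity.
#'
#' @inheritParams term_ancestors
#' @return Character vector of root term ids.
#' @export
ontology_roots <- function(dag, relations = c("is_a", "part_of")) {
  pe <- dag$parents[dag$parents$relation %in% relations, , drop = FALSE]
  live <- dag$terms$id[!dag$terms$obsolete]
  radix_sort(setdiff(live, unique(pe$child)))
}

#' Annotation set
#'
#' A data.frame of protein-to-GO-term association records with columns
#' `protein`, `term`, `provenance` (`"direct"` or `"inferred"`) and
#' `evidence`. Each (protein, term) pair appears at most once per provenance.
#'
#' @param records data.frame with the columns above (`evidence` optional).
#' @return An object of class `annotation_set` (a data.frame).
#' @export
annotation_set <- function(records) {
  if (!"evidence" %in% names(records)) records$evidence <- ""
  stopifnot(all(c("protein", "term", "provenance") %in% names(records)))
  stopifnot(all(records$provenance %in% c("direct", "inferred")))
  records <- records[, c("protein", "term", "provenance", "evidence")]
  key <- paste(records$protein, records$term, records$provenance, sep = "\t")
  if (anyDuplicated(key)) {
    records <- records[!duplicated(key), , drop = FALSE]
  }
  records <- records[radix_order(records$protein, records$term,
                                 records$provenance), , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("annotation_set", "data.frame")
  records
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", sum(x$provenance == "direct"), "direct +",
      sum(x$provenance == "inferred"), "inferred records,",
      length(unique(x$protein)), "proteins,",
      length(unique(x$term)), "terms\n")
  invisible(x)
}

# Case-insensitive protein id canonicalization: ids that differ only by case
# collapse onto the first-seen spelling (species mix gene symbols and locus
# ids with inconsistent case).
canonicalize_proteins <- function(ids) {
  first <- !duplicated(tolower(ids))
  map <- stats::setNames(ids[first], tolower(ids[first]))
  unname(map[tolower(ids)])
}

#' Parse a GAF 2.x annotation file
#'
#' Uses column 2 (object id), column 4 (qualifier), column 5 (GO id) and
#' column 7 (evidence code). Records with a `NOT` qualifier are dropped;
#' records to obsolete or unknown terms are skipped and counted. Duplicate
#' (protein, term) records merge their evidence codes.
#'
#' @param path path to a GAF 2.1/2.2 file.
#' @param dag an [ontology_dag()] used to validate term ids.
#' @return An [annotation_set()] of direct records, with attributes
#'   `n_dropped_not`, `n_dropped_obsolete`, `n_dropped_unknown`.
#' @export
parse_gaf <- function(path, dag) {
  if (!file.exists(path)) stop("GAF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 7
  if (!all(ok)) stop("GAF line with fewer than 7 columns: line ",
                     which(!ok)[1])
  protein <- vapply(fields, `[[`, character(1), 2L)
  qualifier <- vapply(fields, `[[`, character(1), 4L)
  term <- vapply(fields, `[[`, character(1), 5L)
  evidence <- vapply(fields, `[[`, character(1), 7L)
  keep_not <- !grepl("(^|\\|)NOT(\\||$)", qualifier)
  n_not <- sum(!keep_not)
  protein <- protein[keep_not]; term <- term[keep_not]
  evidence <- evidence[keep_not]
  known <- term %in% dag$terms$id
  n_unknown <- sum(!known)
  obsolete_ids <- dag$terms$id[dag$terms$obsolete]
  obs <- term %in% obsolete_ids
  n_obsolete <- sum(known & obs)
  keep <- known & !obs
  protein <- canonicalize_proteins(protein[keep])
  term <- term[keep]; evidence <- evidence[keep]
  if (n_obsolete > 0 || n_unknown > 0) {
    message("parse_gaf: dropped ", n_unknown, " records to unknown terms, ",
            n_obsolete, " to obsolete terms, ", n_not, " NOT-qualified")
  }
  key <- paste(protein, term, sep = "\t")
  merged_ev <- vapply(split(evidence, key), function(e) {
    paste(radix_sort(unique(e)), collapse = "|")
  }, character(1))
  uk <- !duplicated(key)
  ann <- annotation_set(data.frame(
    protein = protein[uk], term = term[uk], provenance = "direct",
    evidence = unname(merged_ev[key[uk]]), stringsAsFactors = FALSE))
  attr(ann, "n_dropped_not") <- n_not
  attr(ann, "n_dropped_obsolete") <- n_obsolete
  attr(ann, "n_dropped_unknown") <- n_unknown
  ann
}

#' Parse a two-column protein/GO TSV annotation file
#'
#' Fallback reader: `protein<TAB>GO id`, optional header.
#'
#' @inheritParams parse_gaf
#' @return An [annotation_set()] of direct records.
#' @export
parse_annotation_tsv <- function(path, dag) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2) stop("annotation TSV needs 2 columns")
  if (!grepl("^GO:", df[1, 2]) && nrow(df) > 1) df <- df[-1, , drop = FALSE]
  keep <- df[[2]] %in% dag$terms$id[!dag$terms$obsolete]
  annotation_set(data.frame(protein = canonicalize_proteins(df[[1]][keep]),
                            term = df[[2]][keep],
                            provenance = "direct", evidence = "",
                            stringsAsFactors = FALSE))
}

#' Write direct annotations to a minimal GAF 2.2 file
#'
#' @param annots an [annotation_set()]; only direct records are written.
#' @param path output path.
#' @param species free-text taxon label for column 13.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annots, path, species = "taxon:0") {
  d <- annots[annots$provenance == "direct", , drop = FALSE]
  ev <- ifelse(nzchar(d$evidence), vapply(strsplit(d$evidence, "|",
               fixed = TRUE), `[[`, character(1), 1L), "IEA")
  lines <- paste("DB", d$protein, d$protein, "", d$term, "REF", ev, "",
                 "P", "", "", "protein", species, "20240101", "DB", "", "",
                 sep = "\t")
  writeLines(c("!gaf-version: 2.2", lines), path)
  invisible(path)
}

#' Propagate annotations to ancestor terms (true-path rule)
#'
#' Adds one inferred record for every (protein, ancestor-of-annotated-term)
#' pair that is not already a direct record. Namespace roots are excluded.
#' Direct records are never downgraded. The operation is idempotent.
#'
#' @param annots an [annotation_set()].
#' @param dag an [ontology_dag()].
#' @param relations relation types traversed for the closure.
#' @return An [annotation_set()] with direct plus inferred records.
#' @export
propagate_annotations <- function(annots, dag,
                                  relations = c("is_a", "part_of")) {
  direct <- annots[annots$provenance == "direct", , drop = FALSE]
  missing <- setdiff(unique(direct$term), dag$terms$id)
  if (length(missing) > 0) {
    stop("annotated terms absent from ontology: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  anc <- ancestor_table(dag, relations)
  roots <- ontology_roots(dag, relations)
  per_term <- lapply(anc[unique(direct$term)], setdiff, y = roots)
  reps <- lengths(per_term[direct$term])
  inferred <- data.frame(
    protein = rep(direct$protein, reps),
    term = unlist(per_term[direct$term], use.names = FALSE),
    provenance = "inferred", evidence = "",
    stringsAsFactors = FALSE)
  direct_key <- paste(direct$protein, direct$term, sep = "\t")
  inf_key <- paste(inferred$protein, inferred$term, sep = "\t")
  inferred <- inferred[!inf_key %in% direct_key & !duplicated(inf_key), ,
                       drop = FALSE]
  annotation_set(rbind(direct[, c("protein", "term", "provenance",
                                  "evidence")], inferred))
}

#' Proteins annotated to a term
#'
#' @param annots an [annotation_set()].
#' @param term a term id.
#' @param include_inferred if `TRUE`, inferred records count too.
#' @return Sorted character vector of protein ids.
#' @export
annotated_proteins <- function(annots, term, include_inferred = TRUE) {
  hit <- annots$term == term
  if (!any(hit)) warning("term has no annotation records: ", term)
  if (!include_inferred) hit <- hit & annots$provenance == "direct"
  radix_sort(unique(annots$protein[hit]))
}
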