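#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' Files are UTF-8 with "." as the decimal mark.
#'
#' @param path File path.
#' @param kind Feature kind tag; see [expression_matrix()].
#' @return An [expression_matrix()]. Missing cells (empty or `NA`) are kept
#'   as `NA`; inferential operations reject them.
#' @export
read_expression_matrix <- function(path, kind = c("miRNA", "gene", "pathway")) {
  kind <- match.arg(kind)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- header[-1L]
  dup <- samples[duplicated(samples)]
  if (length(dup))
    stop("duplicate sample id(s) in header of ", path, ": ",
         paste(unique(dup), collapse = ", "))
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  features <- raw[[1L]]
  dupf <- features[duplicated(features)]
  if (length(dupf))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(dupf), collapse = ", "))
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(samples),
                 dimnames = list(features, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !(is.na(col) | col %in% c("", "NA", "nan", "NaN")))
    if (length(bad))
      stop(sprintf("non-numeric cell in %s at row %d (feature %s), column %s: '%s'",
                   path, bad[1L], features[bad[1L]], samples[j], col[bad[1L]]))
    vals[, j] <- num
  }
  expression_matrix(vals, kind)
}

#' Write an expression matrix as TSV
#'
#' Round-trips through [read_expression_matrix()] to full double precision.
#'
#' @param m Expression matrix (or any matrix with dimnames).
#' @param path Output file path.
#' @param id_column Name of the leading feature-id column in the header.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_column = "feature_id") {
  df <- data.frame(id = rownames(m), as_plain_matrix(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  # format() at 17 significant digits keeps doubles bit-faithful
  for (j in seq_along(df)[-1L])
    df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an MSigDB-style GMT file
#'
#' Each line is `name<TAB>description<TAB>member...`; the description field is
#' stored as the set's collection when non-empty.
#'
#' @param path File path.
#' @return List of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d of %s has %d field(s); need name, description and at least one member",
                   i, path, length(f)))
    out[[i]] <- gene_set(f[1L], f[-(1:2)], collection = f[2L])
  }
  nm <- vapply(out, `[[`, "", "name")
  cl <- vapply(out, `[[`, "", "collection")
  if (anyDuplicated(paste(cl, nm, sep = "\r")))
    stop("duplicate gene set name within a collection in ", path)
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, if (nzchar(s$collection)) s$collection else "na",
            s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a TargetScan-style target-prediction table
#'
#' Duplicate (miRNA, gene) rows are collapsed to their most negative
#' (strongest predicted repression) total context score.
#'
#' @param path TSV file path.
#' @param columns Named character vector mapping the roles `mirna`, `family`,
#'   `gene`, `score` to column names in the file.
#' @return Data frame with columns `mirna`, `family`, `gene`,
#'   `total_context_score`.
#' @export
read_target_predictions <- function(path,
    columns = c(mirna = "mirna", family = "family", gene = "gene",
                score = "total_context_score")) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  missing <- setdiff(unname(columns), names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  out <- data.frame(mirna = as.character(df[[columns[["mirna"]]]]),
                    family = as.character(df[[columns[["family"]]]]),
                    gene = as.character(df[[columns[["gene"]]]]),
                    total_context_score = as.numeric(df[[columns[["score"]]]]),
                    stringsAsFactors = FALSE)
  if (nrow(out) && any(!is.finite(out$total_context_score)))
    stop("non-finite total context score in ", path)
  collapse_target_predictions(out)
}

# Collapse duplicate (miRNA, gene) pairs to the most negative score.
collapse_target_predictions <- function(pred) {
  if (!nrow(pred)) return(pred)
  key <- paste(pred$mirna, pred$gene, sep = "\r")
  if (!anyDuplicated(key)) return(pred)
  ord <- order(key, pred$total_context_score)  # strongest (lowest) first
  pred <- pred[ord, , drop = FALSE]
  pred <- pred[!duplicated(paste(pred$mirna, pred$gene, sep = "\r")), ,
               drop = FALSE]
  rownames(pred) <- NULL
  pred
}

#' Read a clinical survival table
#'
#' @param path TSV or CSV path with columns `time` (months), `event` (0/1),
#'   `age` (years), `stage` (I..IV), `marker` (expression value); an optional
#'   `subject_id` column is kept, otherwise row numbers are used.
#' @return Data frame of validated survival records; `stage` is an ordered
#'   factor I < II < III < IV.
#' @export
read_survival_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("time", "event", "age", "stage", "marker")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  survival_records(
    subject_id = if ("subject_id" %in% names(df)) df$subject_id else seq_len(nrow(df)),
    time = df$time, event = df$event, age = df$age, stage = df$stage,
    marker = df$marker)
}

#' Construct validated survival records
#'
#' @param subject_id Identifiers.
#' @param time Positive follow-up times in months.
#' @param event 1 = event, 0 = censored.
#' @param age Age in years.
#' @param stage Tumor stage labels among I, II, III, IV.
#' @param marker Continuous marker expression value.
#' @return Data frame with `stage` as ordered factor.
#' @export
survival_records <- function(subject_id, time, event, age, stage, marker) {
  time <- as.numeric(time)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be positive")
  event <- as.numeric(event)
  if (!all(event %in% c(0, 1))) stop("event flag must be 0 or 1")
  stage <- as.character(stage)
  ok <- c("I", "II", "III", "IV")
  if (!all(stage %in% ok))
    stop("unknown stage label(s): ",
         paste(unique(stage[!stage %in% ok]), collapse = ", "))
  data.frame(subject_id = as.character(subject_id), time = time,
             event = as.integer(event), age = as.numeric(age),
             stage = factor(stage, levels = ok, ordered = TRUE),
             marker = as.numeric(marker), stringsAsFactors = FALSE)
}

#' Write a network as edge list, node table and GraphML
#'
#' Given a graph from [build_network()], writes `<stem>_edges.tsv` (source,
#' target, weight, sign, relation), `<stem>_nodes.tsv` (id, type, group,
#' direction) and `<stem>.graphml`.
#'
#' @param graph A `network_graph`.
#' @param stem Output path stem (no extension).
#' @return Character vector of the three paths written, invisibly.
#' @export
write_network_edgelist <- function(graph, stem) {
  stopifnot(inherits(graph, "network_graph"))
  paths <- c(edges = paste0(stem, "_edges.tsv"),
             nodes = paste0(stem, "_nodes.tsv"),
             graphml = paste0(stem, ".graphml"))
  write.table(graph$edges, paths[["edges"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(graph$nodes, paths[["nodes"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  igraph::write_graph(as_igraph(graph), paths[["graphml"]], format = "graphml")
  invisible(paths)
}

#' Convert a network graph to an igraph object
#'
#' @param graph A `network_graph`.
#' @return An [igraph::graph_from_data_frame()] directed graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "network_graph"))
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = graph$nodes)
}
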