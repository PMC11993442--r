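# Plain-text I/O: study tables (TSV), truth (JSON) and network exports
# (SIF, GraphML, edge TSV). All writers format numbers with a fixed
# locale-independent "%.15g"/"%.17g" so artifacts are byte-stable.

#' @noRd
writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- fmtNum(df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
}

#' Write a synthetic study to disk
#'
#' Writes `samples.tsv` (per-sample metadata), `matrix.tsv` (samples x
#' metabolites peak heights; column 1 = sample id, header = metabolite
#' names) and `truth.json` (planted parameters). UTF-8, tab-delimited.
#'
#' @param study a `StudyData` list from [generateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(inherits(study, "StudyData"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sPath <- file.path(dir, "samples.tsv")
  mPath <- file.path(dir, "matrix.tsv")
  tPath <- file.path(dir, "truth.json")
  writeTsv(study$birds, sPath)
  x <- metaboliteMatrix(study$experiment)
  mdf <- data.frame(sample_id = rownames(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (j in colnames(x)) mdf[[j]] <- x[, j]
  writeTsv(mdf, mPath)
  truth <- study$truth
  jsonlite::write_json(truth, tPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(samples = sPath, matrix = mPath, truth = tPath))
}

#' Read a study written by [writeStudy()]
#'
#' @param dir directory containing `samples.tsv` and `matrix.tsv`.
#' @param strictPeriods passed to [MetabolomeExperiment()].
#' @return list with `birds` (data.frame) and `experiment`
#'   (a [MetabolomeExperiment-class]).
#' @export
readStudy <- function(dir, strictPeriods = FALSE) {
  sPath <- file.path(dir, "samples.tsv")
  mPath <- file.path(dir, "matrix.tsv")
  birds <- readSamples(sPath)
  if (!file.exists(mPath)) stop(sprintf("matrix file not found: %s", mPath))
  raw <- utils::read.delim(mPath, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (colnames(raw)[1] != "sample_id") {
    stop(sprintf("matrix file %s must have 'sample_id' as first column", mPath))
  }
  x <- as.matrix(raw[, -1, drop = FALSE])
  rownames(x) <- raw$sample_id
  if (!setequal(rownames(x), birds$sample_id) ||
      nrow(x) != nrow(birds)) {
    off <- union(setdiff(rownames(x), birds$sample_id),
                 setdiff(birds$sample_id, rownames(x)))
    stop(sprintf("samples.tsv and matrix.tsv disagree on sample ids: %s",
                 paste(off, collapse = ", ")))
  }
  birds <- birds[match(rownames(x), birds$sample_id), , drop = FALSE]
  meta <- data.frame(
    bird_id = if ("bird_id" %in% colnames(birds)) birds$bird_id else birds$sample_id,
    day = birds$day,
    body_mass_g = birds$body_mass_g, liver_mass_g = birds$liver_mass_g,
    stringsAsFactors = FALSE
  )
  rownames(meta) <- rownames(x)
  experiment <- MetabolomeExperiment(x, meta, normalized = FALSE,
                                     strictPeriods = strictPeriods)
  list(birds = birds, experiment = experiment)
}

#' Export a network to SIF, GraphML or edge TSV
#'
#' SIF lines are `source<TAB>pos|neg<TAB>target` (isolated nodes appear as
#' single-name lines); this format keeps topology and edge sign only.
#' GraphML carries `r`, `p`, `fdr`, `sign` as edge attributes and the
#' period as a graph attribute with full double precision, so
#' [readNetwork()] reproduces the network exactly. Edge TSV keeps the edge
#' table (isolated nodes are not representable). Node ordering is
#' lexicographic, making exports bit-stable.
#'
#' @param net a [PeriodNetwork-class].
#' @param path output file path.
#' @param format "sif", "graphml" or "tsv".
#' @return invisibly, `path`.
#' @export
exportNetwork <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  e <- networkEdges(net)
  if (format == "sif") {
    lines <- character(0)
    if (nrow(e)) lines <- paste(e$from, e$sign, e$to, sep = "\t")
    iso <- setdiff(networkNodes(net), unique(c(e$from, e$to)))
    writeLines(c(lines, iso), path, useBytes = TRUE)
  } else if (format == "tsv") {
    writeTsv(e, path)
  } else {
    xmlEsc <- function(s) {
      s <- gsub("&", "&amp;", s, fixed = TRUE)
      s <- gsub("<", "&lt;", s, fixed = TRUE)
      s <- gsub(">", "&gt;", s, fixed = TRUE)
      gsub("\"", "&quot;", s, fixed = TRUE)
    }
    num17 <- function(x) sprintf("%.17g", x)
    lines <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <key id=\"period\" for=\"graph\" attr.name=\"period\" attr.type=\"string\"/>",
      "  <key id=\"r\" for=\"edge\" attr.name=\"r\" attr.type=\"double\"/>",
      "  <key id=\"p\" for=\"edge\" attr.name=\"p\" attr.type=\"double\"/>",
      "  <key id=\"fdr\" for=\"edge\" attr.name=\"fdr\" attr.type=\"double\"/>",
      "  <key id=\"sign\" for=\"edge\" attr.name=\"sign\" attr.type=\"string\"/>",
      "  <graph edgedefault=\"undirected\">",
      sprintf("    <data key=\"period\">%s</data>", xmlEsc(networkPeriod(net))),
      sprintf("    <node id=\"%s\"/>", xmlEsc(networkNodes(net)))
    )
    if (nrow(e)) {
      lines <- c(lines, sprintf(
        paste0("    <edge source=\"%s\" target=\"%s\">",
               "<data key=\"r\">%s</data><data key=\"p\">%s</data>",
               "<data key=\"fdr\">%s</data><data key=\"sign\">%s</data></edge>"),
        xmlEsc(e$from), xmlEsc(e$to),
        num17(e$r), num17(e$p), num17(e$fdr), xmlEsc(e$sign)))
    }
    lines <- c(lines, "  </graph>", "</graphml>")
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a network exported by [exportNetwork()]
#'
#' @param path file path.
#' @param format "sif", "graphml" or "tsv".
#' @param period period label to assign for formats that do not store one
#'   (SIF, TSV).
#' @return a [PeriodNetwork-class]. SIF input yields NA `r`/`p`/`fdr`
#'   (SIF stores signs only); TSV input has node set = incident nodes.
#' @export
readNetwork <- function(path, format = c("sif", "graphml", "tsv"),
                        period = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("network file not found: %s", path))
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    isEdge <- vapply(parts, length, integer(1)) == 3L
    edges <- if (any(isEdge)) {
      ep <- parts[isEdge]
      data.frame(
        from = vapply(ep, `[[`, character(1), 1L),
        to = vapply(ep, `[[`, character(1), 3L),
        r = NA_real_, p = NA_real_, fdr = NA_real_,
        sign = vapply(ep, `[[`, character(1), 2L),
        stringsAsFactors = FALSE
      )
    } else {
      emptyEdgeFrame()
    }
    iso <- vapply(parts[!isEdge], `[[`, character(1), 1L)
    newPeriodNetwork(period, c(iso, edges$from, edges$to), edges)
  } else if (format == "tsv") {
    e <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c(from = "character", to = "character",
                                          r = "numeric", p = "numeric",
                                          fdr = "numeric", sign = "character"))
    newPeriodNetwork(period, c(e$from, e$to), e)
  } else {
    doc <- xml2::read_xml(path)
    ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
    per <- xml2::xml_text(xml2::xml_find_first(
      doc, "//g:graph/g:data[@key='period']", ns))
    nodes <- xml2::xml_attr(xml2::xml_find_all(doc, "//g:node", ns), "id")
    edgeNodes <- xml2::xml_find_all(doc, "//g:edge", ns)
    getKey <- function(en, key) {
      xml2::xml_text(xml2::xml_find_first(
        en, sprintf("./g:data[@key='%s']", key), ns))
    }
    edges <- if (length(edgeNodes)) {
      data.frame(
        from = xml2::xml_attr(edgeNodes, "source"),
        to = xml2::xml_attr(edgeNodes, "target"),
        r = as.numeric(vapply(edgeNodes, getKey, character(1), "r")),
        p = as.numeric(vapply(edgeNodes, getKey, character(1), "p")),
        fdr = as.numeric(vapply(edgeNodes, getKey, character(1), "fdr")),
        sign = vapply(edgeNodes, getKey, character(1), "sign"),
        stringsAsFactors = FALSE
      )
    } else {
      emptyEdgeFrame()
    }
    newPeriodNetwork(if (is.na(per)) period else per, nodes, edges)
  }
}
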