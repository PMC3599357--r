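#' @importFrom stats cor kmeans p.adjust phyper rnorm runif sd t.test
#'   wilcox.test fisher.test setNames rbinom
#' @importFrom utils read.delim write.table head combn
NULL

# All internal coordinates are 0-based half-open (BED-native); readers
# normalize on the way in, writers convert back to each format's native
# convention.

STRANDS <- c("+", "-", "*")

#' Construct a table of genomic intervals
#'
#' Internal container used throughout the package: a data.frame with columns
#' `chrom`, `start`, `end`, `strand` in 0-based half-open coordinates.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based inclusive start, exclusive end.
#' @param strand strand per interval: "+", "-" or "*" (unstranded).
#' @return data.frame with validated interval columns.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  start <- as.numeric(start); end <- as.numeric(end)
  strand <- rep_len(as.character(strand), length(chrom))
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be numeric")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start")
  if (!all(strand %in% STRANDS))
    stop("strand must be one of '+', '-', '*'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Read a BED file
#'
#' Reads intervals in BED's native 0-based half-open convention (kept as-is
#' internally). Column 6, when present, provides the strand; "." is stored as
#' unstranded ("*").
#'
#' @param path BED file path.
#' @return interval data.frame (see [genomic_intervals()]); columns beyond the
#'   strand add a `name` column when BED column 4 exists.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0)
    return(genomic_intervals(character(0), numeric(0), numeric(0))[0, ])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, 1L)
  bad <- which(ncol < 3L)
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path, ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path, ": non-numeric coordinate")
  bad <- which(end <= start)
  if (length(bad))
    stop("invalid interval at BED line ", bad[1], " in ", path, ": end <= start")
  strand <- rep("*", length(lines))
  has6 <- ncol >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  out <- genomic_intervals(chrom, start, end, strand)
  if (any(ncol >= 4L)) {
    nm <- rep(NA_character_, length(lines))
    nm[ncol >= 4L] <- vapply(fields[ncol >= 4L], `[[`, "", 4L)
    out$name <- nm
  }
  out
}

#' Write intervals to a BED file
#'
#' @param intervals interval data.frame (0-based half-open).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  n <- nrow(intervals)
  name <- if (!is.null(intervals$name)) intervals$name else rep(".", n)
  strand <- intervals$strand
  strand[strand == "*"] <- "."
  df <- data.frame(intervals$chrom, format_coord(intervals$start),
                   format_coord(intervals$end), name, rep(0L, n), strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a genome annotation table
#'
#' The canonical annotation input is a tab-separated table with header columns
#' `id`, `kind` (one of `gene`, `tf`, `mirna`), `chrom`, `start`, `end`,
#' `strand` and optional `host_gene`; coordinates in the file are 1-based
#' inclusive and are converted to the internal 0-based half-open convention.
#' The TSS of a gene is its transcription-oriented 5' position: `start` on the
#' "+" strand, `end - 1` (0-based) on the "-" strand. A miRNA's `host_gene`,
#' when given, must be a gene/TF id present in the table.
#'
#' @param path annotation TSV path.
#' @return an object of class `genome_annotation`: list with data.frames
#'   `genes` (id, gene_type, chrom, start, end, strand, tss) and `mirnas`
#'   (id, chrom, start, end, strand, host_gene).
#' @export
read_annotation <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "kind", "chrom", "start", "end", "strand")
  if (!all(need %in% names(tab)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  if (is.null(tab$host_gene)) tab$host_gene <- NA_character_
  tab$host_gene[tab$host_gene %in% c("", ".", "NA")] <- NA_character_
  bad <- setdiff(unique(tab$kind), c("gene", "tf", "mirna"))
  if (length(bad)) stop("unknown annotation kind: ", paste(bad, collapse = ", "))
  if (anyDuplicated(tab$id)) stop("duplicate ids in annotation")
  strand <- tab$strand
  if (any(strand == ".")) {
    warning("annotation strand '.' treated as '+'")
    strand[strand == "."] <- "+"
  }
  # 1-based inclusive -> 0-based half-open
  start0 <- as.numeric(tab$start) - 1
  end0 <- as.numeric(tab$end)
  if (any(end0 <= start0)) stop("annotation rows with end <= start")
  is_mir <- tab$kind == "mirna"
  genes <- data.frame(
    id = tab$id[!is_mir],
    gene_type = ifelse(tab$kind[!is_mir] == "tf", "TF", "coding"),
    chrom = tab$chrom[!is_mir], start = start0[!is_mir], end = end0[!is_mir],
    strand = strand[!is_mir],
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  mirnas <- data.frame(
    id = tab$id[is_mir], chrom = tab$chrom[is_mir], start = start0[is_mir],
    end = end0[is_mir], strand = strand[is_mir],
    host_gene = tab$host_gene[is_mir],
    stringsAsFactors = FALSE)
  dangling <- setdiff(mirnas$host_gene[!is.na(mirnas$host_gene)], genes$id)
  if (length(dangling))
    stop("miRNA host gene(s) absent from annotation: ",
         paste(dangling, collapse = ", "))
  structure(list(genes = genes, mirnas = mirnas),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes (",
      sum(x$genes$gene_type == "TF"), "TFs ),", nrow(x$mirnas), "miRNAs\n")
  invisible(x)
}

#' Convert a GFF3 file to the canonical annotation TSV
#'
#' Convenience importer: extracts `gene` and `miRNA_primary_transcript` /
#' `pre_miRNA` features from a GFF3 file into the simple annotation table
#' consumed by [read_annotation()]. Only the TSV is canonical.
#'
#' @param gff_path input GFF3 path.
#' @param tsv_path output TSV path.
#' @param tf_ids character vector of ids to mark with kind `tf`.
#' @return `tsv_path`, invisibly.
#' @export
gff3_to_annotation <- function(gff_path, tsv_path, tf_ids = character(0)) {
  lines <- readLines(gff_path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, length, 1L) >= 9L
  fields <- fields[keep]
  type <- vapply(fields, `[[`, "", 3L)
  sel <- type %in% c("gene", "miRNA_primary_transcript", "pre_miRNA")
  fields <- fields[sel]; type <- type[sel]
  attr_field <- vapply(fields, `[[`, "", 9L)
  get_attr <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]+)"), a))
    vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
  }
  id <- get_attr(attr_field, "ID")
  host <- get_attr(attr_field, "Parent")
  kind <- ifelse(type == "gene", "gene", "mirna")
  kind[kind == "gene" & id %in% tf_ids] <- "tf"
  df <- data.frame(
    id = id, kind = kind,
    chrom = vapply(fields, `[[`, "", 1L),
    start = vapply(fields, `[[`, "", 4L),   # GFF3 is already 1-based inclusive
    end = vapply(fields, `[[`, "", 5L),
    strand = vapply(fields, `[[`, "", 7L),
    host_gene = ifelse(kind == "mirna", host, NA),
    stringsAsFactors = FALSE)
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsv_path)
}

#' Read an expression matrix with optional presence calls
#'
#' Expression TSVs have features as rows (first column = feature id) and named
#' timepoint columns. The optional presence TSV has the same shape with
#' TRUE/FALSE (or 1/0) entries.
#'
#' @param path expression TSV path.
#' @param presence_path optional presence-call TSV path; when absent every
#'   value is called present.
#' @return object of class `expr_set`: list with numeric matrix `values` and
#'   logical matrix `presence` (same dimnames).
#' @export
read_expression <- function(path, presence_path = NULL) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  values <- as.matrix(tab)
  if (!is.numeric(values)) stop("non-numeric expression values in ", path)
  if (any(!is.finite(values))) stop("non-finite expression values in ", path)
  presence <- if (is.null(presence_path)) {
    matrix(TRUE, nrow(values), ncol(values), dimnames = dimnames(values))
  } else {
    p <- as.matrix(read.delim(presence_path, row.names = 1,
                              check.names = FALSE))
    storage.mode(p) <- "logical"
    p <- p[rownames(values), colnames(values), drop = FALSE]
    p
  }
  expr_set(values, presence)
}

#' Construct an expression set
#'
#' @param values numeric feature x timepoint matrix with dimnames.
#' @param presence logical matrix of the same shape; default all-present.
#' @return object of class `expr_set`.
#' @export
expr_set <- function(values, presence = NULL) {
  if (is.null(presence))
    presence <- matrix(TRUE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  stopifnot(is.matrix(values), all(dim(values) == dim(presence)))
  if (any(!is.finite(values))) stop("expression values must be finite")
  structure(list(values = values, presence = presence), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$values), "features x", ncol(x$values),
      "timepoints\n")
  invisible(x)
}

#' Write an expression set to TSV
#'
#' @param expr `expr_set` object.
#' @param path output TSV path for values.
#' @param presence_path optional output path for presence calls.
#' @export
write_expression <- function(expr, path, presence_path = NULL) {
  df <- data.frame(feature = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(presence_path)) {
    dp <- data.frame(feature = rownames(expr$presence), expr$presence,
                     check.names = FALSE)
    write.table(dp, presence_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read JASPAR-style position weight matrices
#'
#' Parses the JASPAR text format: a header line `>id name` followed by four
#' rows `A [ n n ... ]` (and C/G/T). Count or frequency matrices are converted
#' to natural-log odds against the background with a pseudocount; a header tag
#' `logodds=natural` or `logodds=bits` marks matrices that are already
#' log-odds (bits are converted to nats).
#'
#' @param path PWM file path (may hold several matrices).
#' @param background base frequency vector (A, C, G, T); must sum to 1.
#' @param pseudocount added to each count before normalization.
#' @return named list of `pwm` objects: list(id, tf, mat, background) where
#'   `mat` is a 4 x L natural-log-odds matrix with rownames ACGT.
#' @export
read_pwms <- function(path, background = rep(0.25, 4), pseudocount = 0.5) {
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no PWM headers ('>') found in ", path)
  out <- list()
  for (i in seq_along(hdr)) {
    from <- hdr[i] + 1
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    if (length(block) < 4) stop("PWM block with fewer than 4 rows in ", path)
    head_toks <- strsplit(sub("^>", "", lines[hdr[i]]), "\\s+")[[1]]
    id <- head_toks[1]
    tf <- if (length(head_toks) >= 2 && !grepl("=", head_toks[2]))
      head_toks[2] else id
    scale <- "counts"
    lo <- grep("logodds=", head_toks, value = TRUE)
    if (length(lo)) scale <- sub("logodds=", "", lo[1])
    extract_nums <- function(l) {
      body <- sub("^\\s*[ACGT]", "", l)
      as.numeric(regmatches(body,
                            gregexpr("-?[0-9.]+(e-?[0-9]+)?", body))[[1]])
    }
    mat <- t(vapply(block[1:4], extract_nums,
                    numeric(length(extract_nums(block[1])))))
    rn <- sub("^\\s*([ACGT]).*", "\\1", block[1:4])
    rownames(mat) <- rn
    mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
    if (ncol(mat) < 4) stop("PWM ", id, " shorter than 4 positions")
    if (scale == "counts") {
      prob <- sweep(mat + pseudocount, 2,
                    colSums(mat + pseudocount), "/")
      mat <- log(sweep(prob, 1, background, "/"))
    } else if (scale == "bits") {
      mat <- mat * log(2)
    } else if (scale != "natural") {
      stop("unknown logodds scale: ", scale)
    }
    out[[id]] <- structure(list(id = id, tf = tf, mat = mat,
                                background = background), class = "pwm")
  }
  out
}

#' Write count PWMs in JASPAR text format
#'
#' @param pwms named list: each element list(id, tf, counts) where counts is a
#'   4 x L integer matrix with rownames ACGT.
#' @param path output path.
#' @export
write_pwms_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id, " ", p$tf), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste0(b, "  [ ", paste(p$counts[b, ], collapse = " "),
                        " ]"), con)
  }
  invisible(path)
}

# ---- regulatory network container ------------------------------------------

NODE_TYPES <- c("TF", "miRNA", "mRNA")
EDGE_EVIDENCE <- c("chipseq", "predicted")

#' Construct a regulatory network
#'
#' Nodes are typed (TF / miRNA / mRNA) with a role and a cluster class; edges
#' are signed and carry their evidence source and the pipeline step that
#' introduced them. Invariants enforced: edge endpoints must be nodes, miRNA
#' outgoing edges are always repressive ("-"), and at most one edge exists per
#' ordered (regulator, target) pair with evidence precedence
#' chipseq > predicted.
#'
#' @param nodes data.frame with columns id, type, role, cluster_class.
#' @param edges data.frame with columns regulator, target, sign, evidence and
#'   optionally step, low_confidence.
#' @return object of class `regnet`.
#' @export
regnet <- function(nodes = NULL, edges = NULL) {
  if (is.null(nodes))
    nodes <- data.frame(id = character(0), type = character(0),
                        role = character(0), cluster_class = character(0),
                        stringsAsFactors = FALSE)
  if (is.null(edges))
    edges <- empty_edges()
  nodes$role <- if (is.null(nodes$role)) rep("target-only", nrow(nodes)) else nodes$role
  nodes$cluster_class <- if (is.null(nodes$cluster_class))
    rep("none", nrow(nodes)) else nodes$cluster_class
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(nodes$type %in% NODE_TYPES)) stop("invalid node type")
  if (nrow(edges)) {
    if (is.null(edges$step)) edges$step <- NA_integer_
    if (is.null(edges$low_confidence)) edges$low_confidence <- FALSE
    missing_nodes <- setdiff(c(edges$regulator, edges$target), nodes$id)
    if (length(missing_nodes))
      stop("edge endpoints not in node set: ",
           paste(missing_nodes, collapse = ", "))
    if (!all(edges$sign %in% c("+", "-"))) stop("edge sign must be + or -")
    if (!all(edges$evidence %in% EDGE_EVIDENCE)) stop("unknown edge evidence")
    type_of <- setNames(nodes$type, nodes$id)
    if (any(type_of[edges$regulator] == "miRNA" & edges$sign != "-"))
      stop("miRNA outgoing edges must have sign '-'")
    # evidence precedence on duplicate ordered pairs
    key <- paste(edges$regulator, edges$target)
    if (anyDuplicated(key)) {
      prec <- match(edges$evidence, EDGE_EVIDENCE)
      ord <- order(key, prec)
      edges <- edges[ord, ][!duplicated(key[ord]), ]
    }
    edges$regulator_type <- unname(type_of[edges$regulator])
    edges$target_type <- unname(type_of[edges$target])
    rownames(edges) <- NULL
  } else {
    edges <- empty_edges()
  }
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "regnet")
}

empty_edges <- function() {
  data.frame(regulator = character(0), target = character(0),
             sign = character(0), evidence = character(0),
             step = integer(0), low_confidence = logical(0),
             regulator_type = character(0), target_type = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.regnet <- function(x, ...) {
  cat("regnet:", nrow(x$nodes), "nodes (",
      sum(x$nodes$type == "TF"), "TF,", sum(x$nodes$type == "miRNA"),
      "miRNA,", sum(x$nodes$type == "mRNA"), "mRNA ),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' @export
summary.regnet <- function(object, ...) {
  e <- object$edges
  cat("Nodes by type/role:\n")
  print(table(type = object$nodes$type, role = object$nodes$role))
  if (nrow(e)) {
    cat("Edges by (regulator type -> target type) and evidence:\n")
    print(table(pair = paste(e$regulator_type, "->", e$target_type),
                evidence = e$evidence))
    cat("Edges by provenance step:\n")
    print(table(step = e$step))
  }
  invisible(object)
}

#' Write a regulatory network
#'
#' Formats: `edge_tsv` (columns regulator, regulator_type, target,
#' target_type, sign, evidence, step), `graphml` (node/edge attributes via
#' igraph) or `sif` (relation `activates`/`represses`). edge_tsv and graphml
#' round-trip losslessly through [read_network()].
#'
#' @param network `regnet` object.
#' @param path output path.
#' @param format one of "edge_tsv", "graphml", "sif".
#' @export
write_network <- function(network, path, format = c("edge_tsv", "graphml",
                                                    "sif")) {
  format <- match.arg(format)
  e <- network$edges
  if (format == "edge_tsv") {
    df <- e[, c("regulator", "regulator_type", "target", "target_type",
                "sign", "evidence", "step")]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    rel <- ifelse(e$sign == "+", "activates", "represses")
    write.table(data.frame(e$regulator, rel, e$target), path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      d = if (nrow(e)) e[, c("regulator", "target", "sign", "evidence",
                             "step")] else
        data.frame(from = character(0), to = character(0)),
      directed = TRUE, vertices = network$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a regulatory network written by [write_network()]
#'
#' @param path input path.
#' @param format "edge_tsv" or "graphml".
#' @param nodes optional node data.frame for edge_tsv input (edge_tsv carries
#'   node types only for connected nodes).
#' @return `regnet` object.
#' @export
read_network <- function(path, format = c("edge_tsv", "graphml"),
                         nodes = NULL) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    e <- read.delim(path, stringsAsFactors = FALSE)
    if (is.null(nodes)) {
      nodes <- unique(rbind(
        data.frame(id = e$regulator, type = e$regulator_type),
        data.frame(id = e$target, type = e$target_type)))
      nodes$role <- "target-only"
      nodes$cluster_class <- "none"
    }
    regnet(nodes, e[, c("regulator", "target", "sign", "evidence", "step")])
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    va <- igraph::as_data_frame(g, what = "vertices")
    ea <- igraph::as_data_frame(g, what = "edges")
    nodes <- data.frame(id = va$name, type = va$type, role = va$role,
                        cluster_class = va$cluster_class,
                        stringsAsFactors = FALSE)
    edges <- if (nrow(ea))
      data.frame(regulator = ea$from, target = ea$to, sign = ea$sign,
                 evidence = ea$evidence, step = as.integer(ea$step),
                 stringsAsFactors = FALSE)
    else NULL
    regnet(nodes, edges)
  }
}

# interval df (0-based half-open) -> IRanges (1-based closed)
as_iranges <- function(intervals) {
  IRanges::IRanges(start = intervals$start + 1, end = intervals$end)
}

# which rows of `query` overlap >= min_bp with any same-chrom row of `subject`
overlaps_any <- function(query, subject, min_bp = 1) {
  hit <- logical(nrow(query))
  if (!nrow(query) || !nrow(subject)) return(hit)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    ov <- IRanges::overlapsAny(as_iranges(query[qi, , drop = FALSE]),
                               as_iranges(subject[si, , drop = FALSE]),
                               minoverlap = min_bp)
    hit[qi] <- ov
  }
  hit
}
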