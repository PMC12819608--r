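# Readers and writers for the package's text formats. All tabular files are
# tab-delimited UTF-8 with a header row and "." as the decimal separator.
# Drug ids are opaque strings; pair files store unordered pairs with
# id_a < id_b lexicographically. Readers reject malformed rows with
# line-numbered errors; writers refuse to emit non-finite values.

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num])
    if (any(!is.finite(df[[cn]])))
      stop("refusing to write non-finite values in column '", cn, "'",
           call. = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

.read_tsv <- function(path, numeric_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          colClasses = NA, comment.char = "")
  for (cn in numeric_cols) {
    if (!cn %in% names(df))
      stop("missing column '", cn, "' in ", path, call. = FALSE)
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad) > 0)
      stop("malformed value in ", basename(path), " line ", bad[1L] + 1L,
           " column '", cn, "'", call. = FALSE)
    df[[cn]] <- v
  }
  df
}

#' Write a cohort to a directory of delimited text files
#'
#' Emits one numeric table per modality (`modality_<m>.tsv`, row = drug), a
#' two-column context table, a three-column co-prescription count table
#' (nonzero unordered pairs), a pair-label table, and the latent cluster
#' assignment (`clusters.tsv`, ground truth for benchmarking).
#'
#' @param cohort `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in seq_along(cohort$modality_features)) {
    mm <- cohort$modality_features[[m]]
    df <- data.frame(drug_id = cohort$drug_ids, mm, stringsAsFactors = FALSE)
    names(df) <- c("drug_id", sprintf("f%03d", seq_len(ncol(mm))))
    .write_tsv(df, file.path(dir, sprintf("modality_%d.tsv", m)))
  }
  ctx <- do.call(rbind, lapply(cohort$drug_ids, function(d) {
    cs <- cohort$context_labels[[d]]
    if (length(cs) == 0) return(NULL)
    data.frame(drug_id = d, context_id = cs, stringsAsFactors = FALSE)
  }))
  .write_tsv(ctx, file.path(dir, "contexts.tsv"))
  o <- cohort$coprescription_counts
  ut <- which(upper.tri(o) & o > 0, arr.ind = TRUE)
  .write_tsv(data.frame(id_a = cohort$drug_ids[ut[, 1L]],
                        id_b = cohort$drug_ids[ut[, 2L]],
                        count = o[ut], stringsAsFactors = FALSE),
             file.path(dir, "coprescriptions.tsv"))
  .write_tsv(cohort$pair_labels, file.path(dir, "pair_labels.tsv"))
  .write_tsv(data.frame(drug_id = cohort$drug_ids,
                        cluster = cohort$cluster_assignment,
                        stringsAsFactors = FALSE),
             file.path(dir, "clusters.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Also accepts externally prepared directories with the same layout; the
#' `clusters.tsv` ground-truth file is optional.
#'
#' @param dir directory path.
#' @return a `synthetic_cohort`-shaped object usable by [train_ddi()].
#' @export
read_cohort <- function(dir) {
  mod_files <- sort(list.files(dir, pattern = "^modality_[0-9]+\\.tsv$",
                               full.names = TRUE))
  if (length(mod_files) == 0) stop("no modality tables in ", dir, call. = FALSE)
  feats <- list()
  drug_ids <- NULL
  for (i in seq_along(mod_files)) {
    df <- .read_tsv(mod_files[i])
    ids <- df$drug_id
    if (is.null(drug_ids)) drug_ids <- ids
    else if (!identical(ids, drug_ids))
      stop("drug id mismatch across modality tables", call. = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric feature in ", mod_files[i], call. = FALSE)
    rownames(m) <- ids
    feats[[i]] <- m
  }
  n <- length(drug_ids)
  ctx_df <- .read_tsv(file.path(dir, "contexts.tsv"))
  contexts <- stats::setNames(
    lapply(drug_ids, function(d) ctx_df$context_id[ctx_df$drug_id == d]),
    drug_ids)
  counts <- matrix(0, n, n, dimnames = list(drug_ids, drug_ids))
  cp <- .read_tsv(file.path(dir, "coprescriptions.tsv"),
                  numeric_cols = "count")
  ia <- match(cp$id_a, drug_ids)
  ib <- match(cp$id_b, drug_ids)
  if (anyNA(ia) || anyNA(ib))
    stop("unknown drug id in coprescriptions.tsv", call. = FALSE)
  counts[cbind(ia, ib)] <- cp$count
  counts[cbind(ib, ia)] <- cp$count
  pairs <- .read_tsv(file.path(dir, "pair_labels.tsv"),
                     numeric_cols = "label")
  pairs$label <- as.integer(pairs$label)
  cluster <- NULL
  cl_path <- file.path(dir, "clusters.tsv")
  if (file.exists(cl_path)) {
    cl <- .read_tsv(cl_path, numeric_cols = "cluster")
    cluster <- as.integer(cl$cluster[match(drug_ids, cl$drug_id)])
  }
  structure(list(n_drugs = n, drug_ids = drug_ids,
                 cluster_assignment = cluster,
                 modality_features = feats,
                 informative_modality_index = NA_integer_,
                 context_labels = contexts,
                 coprescription_counts = counts,
                 pair_labels = pairs, seed = NA_integer_,
                 params = list()),
            class = "synthetic_cohort")
}

#' Write molecular toy graphs as an annotated edge-list text file
#'
#' Format: per molecule a `# molecule <id> atoms=<n>` line, one
#' `# atom <idx> <type> <degree> <aromatic> <charge>` line per atom, then one
#' `<from>\t<to>\t<bond type>` line per undirected bond.
#'
#' @param toys list of `molecular_graph` objects.
#' @param path output file.
#' @export
write_molecular_toys <- function(toys, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (g in toys) {
    writeLines(sprintf("# molecule %s atoms=%d", g$drug_id, g$n_atoms), con)
    for (i in seq_len(g$n_atoms))
      writeLines(sprintf("# atom %d %s %d %d %d", i, g$atoms$type[i],
                         g$atoms$degree[i], g$atoms$aromatic[i],
                         g$atoms$charge[i]), con)
    writeLines(sprintf("%d\t%d\t%s", g$bonds$from, g$bonds$to, g$bonds$type),
               con)
  }
  invisible(path)
}

#' Read molecular toy graphs written by [write_molecular_toys()]
#' @param path input file.
#' @return list of `molecular_graph` objects.
#' @export
read_molecular_toys <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  toys <- list()
  cur <- NULL
  flush_mol <- function(cur) {
    if (is.null(cur)) return(NULL)
    atoms <- do.call(rbind, cur$atoms)
    structure(list(drug_id = cur$id, n_atoms = nrow(atoms),
                   atoms = data.frame(type = atoms[, 1L],
                                      degree = as.integer(atoms[, 2L]),
                                      aromatic = as.integer(atoms[, 3L]),
                                      charge = as.integer(atoms[, 4L]),
                                      stringsAsFactors = FALSE),
                   bonds = do.call(rbind, cur$bonds)),
              class = "molecular_graph")
  }
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    if (grepl("^# molecule ", l)) {
      toys <- c(toys, list(flush_mol(cur)))
      tok <- strsplit(l, " +")[[1L]]
      cur <- list(id = tok[3L], atoms = list(), bonds = list())
    } else if (grepl("^# atom ", l)) {
      tok <- strsplit(l, " +")[[1L]]
      if (length(tok) != 7L)
        stop("malformed atom line ", ln, " in ", basename(path), call. = FALSE)
      cur$atoms[[length(cur$atoms) + 1L]] <- tok[4:7]
    } else if (nzchar(trimws(l))) {
      tok <- strsplit(l, "\t")[[1L]]
      fr <- suppressWarnings(as.integer(tok[1L]))
      to <- suppressWarnings(as.integer(tok[2L]))
      if (length(tok) != 3L || is.na(fr) || is.na(to))
        stop("malformed bond line ", ln, " in ", basename(path), call. = FALSE)
      cur$bonds[[length(cur$bonds) + 1L]] <-
        data.frame(from = fr, to = to, type = tok[3L], stringsAsFactors = FALSE)
    }
  }
  toys <- c(toys, list(flush_mol(cur)))
  toys[!vapply(toys, is.null, logical(1))]
}

#' Read and write SMILES files
#'
#' Dialect: one `ID<TAB>SMILES` record per line, `#` comments allowed.
#'
#' @param path file path.
#' @return data frame with `id` and `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(!grepl("^\\s*(#|$)", lines))
  tok <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(tok) != 2L)
  if (length(bad) > 0)
    stop("malformed SMILES line ", keep[bad[1L]], " in ", basename(path),
         call. = FALSE)
  data.frame(id = vapply(tok, `[`, "", 1L),
             smiles = vapply(tok, `[`, "", 2L), stringsAsFactors = FALSE)
}

#' @rdname read_smiles_file
#' @param df data frame with `id` and `smiles` columns.
#' @export
write_smiles_file <- function(df, path) {
  writeLines(paste(df$id, df$smiles, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Write a square matrix with drug-id row/column labels
#' @param m matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(m, path) {
  if (any(!is.finite(m))) stop("refusing to write non-finite matrix", call. = FALSE)
  df <- data.frame(drug_id = rownames(m), as.data.frame(unclass(m)),
                   stringsAsFactors = FALSE)
  names(df) <- c("drug_id", colnames(m))
  .write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in ", basename(path), call. = FALSE)
  rownames(m) <- df$drug_id
  m
}

#' Write weighted edges of a graph or similarity matrix
#'
#' Three columns `id_a`, `id_b`, `weight`, one row per nonzero unordered pair.
#'
#' @param m symmetric matrix with drug-id dimnames.
#' @param path output file.
#' @export
write_edge_list <- function(m, path) {
  ut <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  ids <- rownames(m)
  .write_tsv(data.frame(id_a = ids[ut[, 1L]], id_b = ids[ut[, 2L]],
                        weight = m[ut], stringsAsFactors = FALSE), path)
}

#' Export an attention map as three-column delimited text
#'
#' One row per (source, target) pair with a nonzero attention weight.
#'
#' @param m attention matrix with source rows and target columns (dimnames
#'   used as identifiers when present).
#' @param path output file.
#' @export
write_attention_map <- function(m, path) {
  src <- rownames(m)
  if (is.null(src)) src <- as.character(seq_len(nrow(m)))
  tgt <- colnames(m)
  if (is.null(tgt)) tgt <- as.character(seq_len(ncol(m)))
  nz <- which(m != 0, arr.ind = TRUE)
  .write_tsv(data.frame(source = src[nz[, 1L]], target = tgt[nz[, 2L]],
                        weight = m[nz], stringsAsFactors = FALSE), path)
}

#' Write a run manifest next to CLI outputs
#'
#' Records the command, a config snapshot, md5 digests of the input files,
#' the seed, the package version and a timestamp.
#'
#' @param dir output directory.
#' @param command subcommand name.
#' @param config list snapshot of the configuration used.
#' @param inputs character vector of input file paths.
#' @param seed integer seed of the run.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, config, inputs = character(0),
                           seed = NA_integer_) {
  digests <- if (length(inputs) > 0) {
    d <- tools::md5sum(inputs[file.exists(inputs)])
    as.list(d)
  } else list()
  manifest <- list(command = command,
                   config = config,
                   input_digests = digests,
                   seed = seed,
                   artifact_version = as.character(utils::packageVersion("interdrug")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
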