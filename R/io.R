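#' Read a long-format association file
#'
#' The file is tab-separated with header `drug_id  side_effect_id  label`;
#' one known association per row, the label recording provenance
#' (`clinical`, `sider_post`, `offsides_post`). Lines starting with `#` are
#' comments. Duplicate rows are collapsed with a warning. Drugs with fewer
#' than `min_se_per_drug` associations (after label filtering) are dropped,
#' mirroring the study-inclusion rule of at least five clinical-trial side
#' effects per drug.
#'
#' @param path file path.
#' @param label_filter optional character vector of labels to keep.
#' @param min_se_per_drug minimum associations per retained drug (default
#'   0 = keep all).
#' @return an [association_matrix()].
#' @export
read_associations <- function(path, label_filter = NULL,
                              min_se_per_drug = 0L) {
  df <- read_tsv_checked(path, c("drug_id", "side_effect_id", "label"))
  if (!is.null(label_filter)) {
    df <- df[df$label %in% label_filter, , drop = FALSE]
  }
  if (!nrow(df)) stop("no associations", if (!is.null(label_filter)) {
    paste0(" with label(s) ", paste(label_filter, collapse = ", "))
  }, " in ", path)
  key <- paste(df$drug_id, df$side_effect_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate association row(s) collapsed")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  if (min_se_per_drug > 0L) {
    counts <- table(df$drug_id)
    keep <- names(counts)[counts >= min_se_per_drug]
    dropped <- length(counts) - length(keep)
    if (dropped > 0L) {
      message(dropped, " drug(s) dropped below the ", min_se_per_drug,
              "-association floor")
    }
    df <- df[df$drug_id %in% keep, , drop = FALSE]
    if (!nrow(df)) stop("no drugs satisfy the association floor")
  }
  association_from_pairs(df$drug_id, df$side_effect_id)
}

#' Write an association matrix in long format
#'
#' @param x binary association matrix.
#' @param path output path.
#' @param label provenance label for every row (default `"clinical"`).
#' @param seed optional integer recorded in the header comment.
#' @export
write_associations <- function(x, path, label = "clinical", seed = NULL) {
  idx <- which(x == 1, arr.ind = TRUE)
  df <- data.frame(drug_id = rownames(x)[idx[, 1]],
                   side_effect_id = colnames(x)[idx[, 2]],
                   label = label, stringsAsFactors = FALSE)
  df <- df[order(df$drug_id, df$side_effect_id), , drop = FALSE]
  write_with_header(df, path, seed = seed)
}

#' Read / write a similarity graph edge list
#'
#' Tab-separated columns `entity_a  entity_b  weight`, undirected. A file
#' listing both directions of a pair with different weights is rejected as
#' inconsistent.
#'
#' @param path file path.
#' @param entity_ids optional entity universe; defaults to the identifiers
#'   observed in the file (sorted).
#' @param name graph label; defaults to the file name without extension.
#' @return a [similarity_graph()].
#' @export
read_graph <- function(path, entity_ids = NULL, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- read_tsv_checked(path, c("entity_a", "entity_b", "weight"))
  df$weight <- as.numeric(df$weight)
  if (anyNA(df$weight)) stop("non-numeric weight in ", path)
  key <- ifelse(df$entity_a < df$entity_b,
                paste(df$entity_a, df$entity_b, sep = "\r"),
                paste(df$entity_b, df$entity_a, sep = "\r"))
  w_by_key <- split(df$weight, key)
  incons <- vapply(w_by_key, function(w) max(w) - min(w) > 1e-12, logical(1))
  if (any(incons)) {
    stop("asymmetric duplicate edge(s) in ", path, ": ",
         paste(gsub("\r", "--", names(w_by_key)[incons])[1:min(3, sum(incons))],
               collapse = ", "))
  }
  if (is.null(entity_ids)) {
    entity_ids <- sort(unique(c(df$entity_a, df$entity_b)))
  }
  similarity_graph(entity_ids,
                   edges = data.frame(from = df$entity_a, to = df$entity_b,
                                      weight = df$weight),
                   name = name)
}

#' @rdname read_graph
#' @param graph a [similarity_graph()] to write.
#' @param seed optional integer recorded in the header comment.
#' @export
write_graph <- function(graph, path, seed = NULL) {
  a <- graph$adjacency
  ut <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  df <- data.frame(entity_a = graph$entity_ids[ut[, 1]],
                   entity_b = graph$entity_ids[ut[, 2]],
                   weight = sprintf("%.17g", a[ut]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$entity_a, df$entity_b), , drop = FALSE]
  write_with_header(df, path, seed = seed)
}

#' Read / write a dense named matrix
#'
#' Tab-separated dump with column identifiers in the header and row
#' identifiers in the first column (`id`). Values are printed at 17
#' significant digits, so a write/read round trip is bit-exact for doubles.
#'
#' @param path file path.
#' @return a numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "id") stop("matrix file must start with an 'id' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  m
}

#' @rdname read_matrix
#' @param m numeric matrix with dimnames.
#' @param seed optional integer recorded in the header comment.
#' @export
write_matrix <- function(m, path, seed = NULL) {
  df <- data.frame(id = rownames(m),
                   apply(m, 2L, function(col) sprintf("%.17g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", colnames(m))
  write_with_header(df, path, seed = seed)
}

#' Read a hierarchy and its entity annotations
#'
#' The hierarchy file is tab-separated `child_code  parent_code`; the
#' annotation file is `entity_id  leaf_code`, one code per row.
#'
#' @param hierarchy_path,annotations_path file paths.
#' @return a [hierarchy()].
#' @export
read_hierarchy <- function(hierarchy_path, annotations_path) {
  edges <- read_tsv_checked(hierarchy_path, c("child_code", "parent_code"))
  ann_df <- read_tsv_checked(annotations_path, c("entity_id", "leaf_code"))
  ann <- split(ann_df$leaf_code, ann_df$entity_id)
  hierarchy(data.frame(child = edges$child_code, parent = edges$parent_code),
            ann)
}

#' @rdname read_hierarchy
#' @param h a [hierarchy()] to write.
#' @param seed optional integer recorded in the header comments.
#' @export
write_hierarchy <- function(h, hierarchy_path, annotations_path,
                            seed = NULL) {
  write_with_header(stats::setNames(h$parent_edges,
                                    c("child_code", "parent_code")),
                    hierarchy_path, seed = seed)
  ann_df <- data.frame(
    entity_id = rep(names(h$annotations), lengths(h$annotations)),
    leaf_code = unlist(h$annotations, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_with_header(ann_df, annotations_path, seed = seed)
}

#' Read an entity feature file
#'
#' Tab-separated `entity_id  token`, one token per row.
#'
#' @param path file path.
#' @return named list mapping entities to token vectors.
#' @export
read_features <- function(path) {
  df <- read_tsv_checked(path, c("entity_id", "token"))
  lapply(split(df$token, df$entity_id), unique)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line (tabs also accepted as separator);
#' `#` starts a comment. Values that parse as numbers are returned numeric.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "[=\t]", perl = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop("malformed config line ", i, ": '", lines[i], "'")
    }
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Build a fit control from configuration keys
#'
#' Looks up keys of the form `<prefix>.l2`, `<prefix>.l1`,
#' `<prefix>.diag_penalty`, `<prefix>.tol`, `<prefix>.max_iter`,
#' `<prefix>.init_upper`, `<prefix>.seed` and
#' `<prefix>.graph_weights.<name>` in a [read_config()] list; missing keys
#' keep the [gsem_control()] defaults.
#'
#' @param cfg named list from [read_config()].
#' @param prefix `"h"` or `"w"` (or any custom block name).
#' @param seed fallback seed when the config has none.
#' @return a [gsem_control()].
#' @export
control_from_config <- function(cfg, prefix, seed = 1L) {
  pick <- function(key, default) {
    full <- paste0(prefix, ".", key)
    if (!is.null(cfg[[full]])) cfg[[full]] else default
  }
  gw_keys <- grep(paste0("^", prefix, "\\.graph_weights\\."), names(cfg),
                  value = TRUE)
  gw <- stats::setNames(as.numeric(unlist(cfg[gw_keys])),
                        sub(paste0("^", prefix, "\\.graph_weights\\."), "",
                            gw_keys))
  gsem_control(l2 = pick("l2", 0), l1 = pick("l1", 0), graph_weights = gw,
               diag_penalty = pick("diag_penalty", 1e4),
               tol = pick("tol", 1e-2),
               max_iter = pick("max_iter", 500L),
               init_upper = pick("init_upper", 0.01),
               seed = pick("seed", seed))
}

# --- shared low-level helpers -------------------------------------------

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e)))
  if (!nrow(df)) stop("empty file: ", path)
  if (!all(required_cols %in% names(df))) {
    stop(path, " must have columns: ", paste(required_cols, collapse = ", "))
  }
  bad <- which(apply(df[required_cols], 1L,
                     function(r) any(is.na(r) | !nzchar(r))))
  if (length(bad)) {
    stop("malformed row at line ", bad[1] + 1L, " of ", path)
  }
  df
}

write_with_header <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# gsem ",
                    as.character(utils::packageVersion("gsem"))), con)
  if (!is.null(seed)) writeLines(paste0("# seed ", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
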