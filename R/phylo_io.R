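# Tree and trait-table input/output, validation, pruning, rescaling.

#' Read a time-calibrated tree
#'
#' Reads a rooted tree in Newick or Nexus format (Nexus translate blocks are
#' handled), validates it, and resolves any polytomies into binary nodes with
#' zero-length edges (deterministically, no randomness), since all downstream
#' likelihood machinery assumes binary trees.
#'
#' @param path Path to the tree file.
#' @param format `"auto"` (default; sniffs a `#NEXUS` header), `"newick"`, or
#'   `"nexus"`.
#' @return A `phylo` object with unique tip labels and non-negative edge
#'   lengths.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("(A:1.0,B:1.0);", tf)
#' tr <- read_tree(tf)
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  tree <- tryCatch(
    suppressWarnings(
      if (format == "newick") ape::read.tree(path) else ape::read.nexus(path)),
    error = function(e) stop("failed to parse '", path, "' as ", format,
                             ": ", conditionMessage(e), call. = FALSE))
  if (inherits(tree, "multiPhylo")) {
    warning("file contains ", length(tree), " trees; using the first")
    tree <- tree[[1]]
  }
  if (is.null(tree)) stop("failed to parse '", path, "' as ", format)
  validate_tree(tree)
}

#' Validate a tree for downstream analyses
#'
#' Checks unique tip labels and non-negative edge lengths; resolves
#' polytomies to binary nodes with zero-length edges (with a warning).
#'
#' @param tree A `phylo` object.
#' @return The validated (possibly dichotomised) tree.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no edge lengths")
  if (any(tree$edge.length < 0)) stop("negative edge lengths present")
  if (!ape::is.binary.phylo(tree) || !ape::is.rooted(tree)) {
    warning("polytomies (incl. an unrooted basal trichotomy) resolved to ",
            "binary rooted form with zero-length edges")
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' Write a tree to file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @param format `"newick"` or `"nexus"` (Nexus output uses a translate
#'   table).
#' @return The path, invisibly.
#' @export
write_tree <- function(tree, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (format == "newick") {
    ok <- ape::write.tree(tree, file = path, digits = 12)
  } else {
    ape::write.nexus(tree, file = path, translate = TRUE)
  }
  if (!file.exists(path)) stop("could not write to ", path)
  invisible(path)
}

#' Prune a tree to a set of taxa
#'
#' Returns the induced subtree on `keep`; edge lengths across collapsed
#' degree-two nodes are summed, so root-to-tip depths of kept taxa (and
#' ultrametricity) are preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2) stop("need at least 2 taxa to keep")
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Check whether a tree is ultrametric
#'
#' @param tree A `phylo` object.
#' @param rel_tol Relative tolerance on root-to-tip depth variation.
#' @return List with `ultrametric` (logical) and `max_deviation` (the
#'   maximum relative deviation of any tip depth from the mean depth).
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  md <- mean(depths)
  dev <- if (md > 0) max(abs(depths - md)) / md else 0
  list(ultrametric = dev <= rel_tol, max_deviation = dev)
}

#' Rescale branch lengths to a target mean edge length
#'
#' Rescaling a chronogram so rate parameters are of order one is standard
#' practice before MCMC on transition rates; rates estimated on the scaled
#' tree multiplied by `scale_factor` recover original-time-unit rates.
#'
#' @param tree A `phylo` object with positive total length.
#' @param target_mean_edge Desired mean edge length (default 0.1).
#' @return An object of class `scaled_tree`: list with `tree` (rescaled) and
#'   `scale_factor` (scaled = original x factor).
#' @export
scale_branch_lengths <- function(tree, target_mean_edge = 0.1) {
  m <- mean(tree$edge.length)
  if (!is.finite(m) || m <= 0) stop("tree has zero or undefined total length")
  f <- target_mean_edge / m
  tree$edge.length <- tree$edge.length * f
  structure(list(tree = tree, scale_factor = f), class = "scaled_tree")
}

#' Read a species-by-trait table
#'
#' Reads a comma- or tab-delimited table with a mandatory `species` column.
#' `NA`, empty cells and `?` are treated as missing; non-numeric cells in
#' trait columns become missing with a warning.  Rows sharing a species name
#' (multiple sampled populations) are averaged for continuous traits;
#' disagreeing binary values collapse to missing with a warning.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator; `NULL` (default) sniffs tab versus comma.
#' @param drop_species Optional character vector of species rows to drop
#'   before averaging (e.g. duplicate populations kept under distinct names).
#' @param binary_columns Columns treated as presence/absence codes.
#' @return A data frame with one row per species.
#' @export
read_trait_table <- function(path, sep = NULL, drop_species = NULL,
                             binary_columns = c("internal_fertilization",
                                                "viviparity", "placentotrophy",
                                                "superfetation", "courtship",
                                                "dichromatism",
                                                "ornamentation")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("NA", "", "?"),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (!"species" %in% names(raw)) stop("missing mandatory 'species' column")
  if (!is.null(drop_species)) raw <- raw[!(raw$species %in% drop_species), ]
  num_cols <- setdiff(names(raw), c("species", "population"))
  for (cn in num_cols) {
    if (is.character(raw[[cn]])) {
      conv <- suppressWarnings(as.numeric(raw[[cn]]))
      bad <- !is.na(raw[[cn]]) & is.na(conv)
      if (any(bad))
        warning(sum(bad), " unparseable cell(s) in column '", cn,
                "' set to missing")
      raw[[cn]] <- conv
    }
  }
  binary_columns <- intersect(binary_columns, num_cols)
  for (cn in binary_columns) {
    v <- raw[[cn]]
    if (any(!v[!is.na(v)] %in% c(0, 1)))
      stop("column '", cn, "' contains values outside {0, 1, NA}")
  }
  # average multi-population rows per species
  if (anyDuplicated(raw$species)) {
    agg <- lapply(num_cols, function(cn) {
      tapply(raw[[cn]], raw$species, function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) return(NA_real_)
        if (cn %in% binary_columns) {
          if (length(unique(v)) > 1L) return(NA_real_)
          return(v[1])
        }
        mean(v)
      })
    })
    sp <- sort(unique(raw$species))
    out <- data.frame(species = sp, stringsAsFactors = FALSE)
    for (i in seq_along(num_cols)) out[[num_cols[i]]] <- as.numeric(agg[[i]][sp])
    for (cn in binary_columns) {
      pops <- tapply(raw[[cn]], raw$species, function(v) {
        v <- v[!is.na(v)]; length(unique(v)) > 1L
      })
      if (any(pops, na.rm = TRUE))
        warning("binary column '", cn, "' disagrees across populations of ",
                sum(pops, na.rm = TRUE), " species; set to missing")
    }
  } else {
    out <- raw[, c("species", num_cols), drop = FALSE]
    rownames(out) <- NULL
  }
  if (anyDuplicated(out$species)) stop("duplicate species after averaging")
  comp <- c("courtship", "dichromatism", "ornamentation")
  if (all(comp %in% names(out)) && !"sexual_selection_index" %in% names(out))
    out$sexual_selection_index <- sexual_selection_index(
      out$courtship, out$dichromatism, out$ornamentation)
  out
}
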