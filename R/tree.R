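#' Parse a newick string into a time tree
#'
#' Reads a single rooted tree with branch lengths (in Myr) from a newick
#' string. Tip labels must be unique after canonicalisation (surrounding
#' whitespace trimmed; spaces and underscores equivalent).
#'
#' @param text A newick string, e.g. `"((A:1,B:1):1,C:2);"`.
#' @return An [ape::read.tree()] `phylo` object with branch lengths.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    stop_phybite("`text` must be a single newick string.")
  }
  # Balance scan so malformed input reports the offending position.
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop_phybite(sprintf(
          "Malformed newick: unmatched ')' at position %d.", i))
      }
    }
  }
  if (depth != 0L) {
    stop_phybite(sprintf(
      "Malformed newick: %d unclosed '(' (string ends at position %d).",
      depth, length(chars)))
  }
  if (!grepl(";\\s*$", text)) {
    stop_phybite(sprintf(
      "Malformed newick: missing terminal ';' at position %d.", nchar(text)))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree)) {
    stop_phybite("Malformed newick: could not be parsed.")
  }
  if (is.null(tree$edge.length)) {
    stop_phybite("Newick tree must carry branch lengths.")
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0)) {
    stop_phybite("All branch lengths must be finite and >= 0.")
  }
  tree$tip.label <- norm_label(tree$tip.label)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    stop_phybite(sprintf("Duplicate tip labels: %s",
                         paste(dup, collapse = ", ")))
  }
  tree
}

#' Write a tree as newick
#'
#' @param tree A `phylo` tree.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @param digits Significant digits for branch lengths (default 9).
#' @return The newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 9) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Node and tip ages of a time tree
#'
#' Ages are in Ma before present with the present at 0; the root age is the
#' maximum root-to-tip path length, i.e. the deepest tip is taken to reach
#' the present (or supply `root_age` for trees of extinct taxa only).
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param root_age Optional root age in Ma; defaults to the tree height.
#' @return A tibble with columns `node`, `label` (tips only), `age_ma`,
#'   `is_tip`.
#' @export
node_ages <- function(tree, root_age = NULL) {
  stopifnot(inherits(tree, "phylo"))
  depth <- ape::node.depth.edgelength(tree)
  ntip <- ape::Ntip(tree)
  if (is.null(root_age)) root_age <- max(depth[seq_len(ntip)])
  tibble::tibble(
    node = seq_along(depth),
    label = c(tree$tip.label, rep(NA_character_,
                                  length(depth) - ntip)),
    age_ma = root_age - depth,
    is_tip = seq_along(depth) <= ntip
  )
}

#' Read a stratigraphic-range table
#'
#' Expects a CSV with header `taxon,fad_ma,lad_ma` (first and last appearance
#' dates in Ma; `fad_ma >= lad_ma >= 0`).
#'
#' @param file Path to the CSV file.
#' @return A validated tibble.
#' @export
read_strat_ranges <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(taxon = "character"))
  validate_strat_ranges(df)
}

validate_strat_ranges <- function(ranges) {
  require_columns(ranges, c("taxon", "fad_ma", "lad_ma"), "strat-range table")
  check_number(ranges$fad_ma, "fad_ma", lower = 0)
  check_number(ranges$lad_ma, "lad_ma", lower = 0)
  if (any(ranges$fad_ma < ranges$lad_ma)) {
    bad <- ranges$taxon[ranges$fad_ma < ranges$lad_ma]
    stop_phybite(sprintf("FAD must be >= LAD; violated for: %s",
                         paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(ranges)
}

#' Time-scale terminal branches from stratigraphic ranges
#'
#' Extends the terminal branch of each fossil tip so that it ends at the
#' taxon's last appearance date (LAD): the branch spans from the divergence
#' date down to the LAD, covering the full FAD-LAD range. Tips not listed in
#' `ranges` are treated as extant and extended to the present (0 Ma). The
#' input tree's internal node ages (from its branch lengths) are taken as the
#' divergence dates; `root_age` fixes the absolute time scale and defaults to
#' the tree height (deepest tip at present).
#'
#' @param tree A `phylo` tree whose node depths encode divergence dates.
#' @param ranges A data frame `taxon,fad_ma,lad_ma` (see
#'   [read_strat_ranges()]).
#' @param extant Optional character vector of extant tip labels. When given,
#'   every tip must appear in `ranges` or in `extant`.
#' @param root_age Optional root age in Ma.
#' @return The re-scaled `phylo` tree (generally non-ultrametric).
#' @export
timescale_fad_lad <- function(tree, ranges, extant = NULL, root_age = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ranges <- validate_strat_ranges(ranges)
  ranges$taxon <- norm_label(ranges$taxon)
  tips <- norm_label(tree$tip.label)
  if (!is.null(extant)) {
    extant <- norm_label(extant)
    missing <- setdiff(tips, c(ranges$taxon, extant))
    if (length(missing) > 0) {
      stop_phybite(sprintf(
        "Tips missing from both `ranges` and `extant`: %s",
        paste(missing, collapse = ", ")))
    }
  }
  unknown <- setdiff(ranges$taxon, tips)
  if (length(unknown) > 0) {
    stop_phybite(sprintf("Range taxa not in tree: %s",
                         paste(unknown, collapse = ", ")))
  }
  ages <- node_ages(tree, root_age = root_age)$age_ma
  ntip <- ape::Ntip(tree)
  out <- tree
  for (i in seq_len(nrow(out$edge))) {
    child <- out$edge[i, 2]
    if (child > ntip) next
    parent <- out$edge[i, 1]
    div_age <- ages[parent]
    lab <- tips[child]
    j <- match(lab, ranges$taxon)
    target_age <- if (is.na(j)) 0 else ranges$lad_ma[j]
    if (!is.na(j)) {
      if (ranges$lad_ma[j] > div_age + 1e-9) {
        stop_phybite(sprintf(
          "LAD (%.6g Ma) of %s is older than its divergence date (%.6g Ma).",
          ranges$lad_ma[j], lab, div_age))
      }
      if (ranges$fad_ma[j] > div_age + 1e-9) {
        rlang::warn(sprintf(
          "FAD (%.6g Ma) of %s predates its divergence date (%.6g Ma); the full range cannot lie on the terminal branch.",
          ranges$fad_ma[j], lab, div_age))
      }
    }
    out$edge.length[i] <- div_age - target_age
  }
  out
}

#' Resolve zero-length internal branches by the "equal" rule
#'
#' Each maximal connected run of zero-length internal branches is pooled with
#' the nearest ancestral branch of positive length; that ancestor's duration
#' is shared out by sliding the intervening node ages to evenly spaced
#' positions, so every branch in the pool receives an equal share along each
#' root-to-anchor path. All root-to-tip distances are preserved exactly.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param tol Branches shorter than this (Myr) count as zero (default 1e-12).
#' @return The adjusted `phylo` tree.
#' @export
resolve_zero_branches_equal <- function(tree, tol = 1e-12) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  out <- tree
  for (pass in seq_len(ape::Nnode(tree) + 1L)) {
    depth <- ape::node.depth.edgelength(out)
    edge <- out$edge
    len <- out$edge.length
    zero <- which(len <= tol & edge[, 2] > ntip)
    if (length(zero) == 0) break
    # Cluster zero edges that chain into each other.
    zchild <- edge[zero, 2]
    parent_of <- setNames(edge[, 1], edge[, 2])
    # Topmost cluster: pick the zero edge whose parent is not itself a
    # zero-edge child, at minimal depth (process top-down).
    top_edges <- zero[!(edge[zero, 1] %in% zchild)]
    ord <- order(depth[edge[top_edges, 1]])
    e_top <- top_edges[ord[1]]
    p_top <- edge[e_top, 1]
    if (p_top == root) {
      stop_phybite(
        "Zero-length branch at the root: no positive-length ancestral branch can donate time.")
    }
    donor <- which(edge[, 2] == p_top)
    # donor must be positive: if it were zero its child would be in zchild.
    a_u <- -depth[edge[donor, 1]]     # work in -depth (age up to a constant)
    a_0 <- -depth[p_top]
    # Collect the cluster: p_top plus every zero-edge child reachable from it
    # through zero edges.
    pool <- p_top
    frontier <- p_top
    repeat {
      nxt <- edge[zero, 2][edge[zero, 1] %in% frontier]
      nxt <- setdiff(nxt, pool)
      if (length(nxt) == 0) break
      pool <- c(pool, nxt)
      frontier <- nxt
    }
    # Edge-depth of each pool node below the donor parent.
    d <- setNames(integer(length(pool)), pool)
    d[as.character(p_top)] <- 1L
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (v in pool) {
        pv <- parent_of[as.character(v)]
        if (v != p_top && as.character(pv) %in% names(d) &&
            d[as.character(v)] == 0L) {
          d[as.character(v)] <- d[as.character(pv)] + 1L
          changed <- TRUE
        }
      }
    }
    D <- max(d)
    span <- a_u - a_0
    # New age for pool node v: evenly spaced between donor parent and the
    # deepest pool level; nodes at depth D keep their age.
    new_age <- a_u - (d / D) * span
    # Recompute the affected edge lengths from the slid ages.
    node_age <- -depth
    node_age[as.integer(names(new_age))] <- new_age
    for (i in seq_len(nrow(edge))) {
      p <- edge[i, 1]; ch <- edge[i, 2]
      if (p %in% pool || ch %in% pool) {
        out$edge.length[i] <- node_age[p] - node_age[ch]
      }
    }
  }
  len <- out$edge.length
  if (any(len <= tol & out$edge[, 2] > ntip)) {
    stop_phybite("Failed to resolve all zero-length internal branches.")
  }
  out
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Entry (i, j) is the path length (Myr) from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip path
#' lengths. Under Brownian motion, trait covariance is proportional to this
#' matrix. Polytomies are handled natively.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param taxa Optional ordered character vector of tip labels; the matrix
#'   rows/columns follow this order. Default: all tips in tree order.
#' @return A symmetric positive semi-definite matrix with tip-label dimnames.
#' @examples
#' phylo_vcv(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
phylo_vcv <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  V <- ape::vcv.phylo(tree)
  labs <- norm_label(rownames(V))
  rownames(V) <- colnames(V) <- labs
  if (is.null(taxa)) return(V)
  want <- norm_label(taxa)
  idx <- match(want, labs)
  if (anyNA(idx)) {
    stop_phybite(sprintf("Taxa not found in tree: %s",
                         paste(taxa[is.na(idx)], collapse = ", ")))
  }
  V[idx, idx, drop = FALSE]
}
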