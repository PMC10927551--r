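#' Parse `species|gene|chromosome` leaf labels
#'
#' @param labels character vector of leaf labels.
#' @param label_regex regex with three capture groups (species, gene,
#'   chromosome).
#' @return data frame `label`, `species`, `gene`, `chromosome` (NA fields for
#'   labels that do not match).
#' @export
parse_leaf_labels <- function(labels,
                              label_regex = "^([^|]+)\\|([^|]+)\\|([^|]+)$") {
  m <- regmatches(labels, regexec(label_regex, labels))
  get <- function(i) vapply(m, function(x)
    if (length(x) == 4L) x[i + 1L] else NA_character_, "")
  data.frame(label = labels, species = get(1L), gene = get(2L),
             chromosome = get(3L), stringsAsFactors = FALSE)
}

#' Label the gnathostome backbone of a gene tree
#'
#' Roots the tree on its outgroup leaves and assigns every reference-species
#' leaf to one of the four post-2R clades A/B/C/D by its chromosome of
#' origin, then verifies that the reference backbone is compatible with the
#' expected `((A,B),(C,D))` topology (each clade monophyletic, and each 1R
#' pair monophyletic, after pruning test and unknown leaves). Trees failing
#' verification are flagged unusable rather than partially scored.
#'
#' @param tree an `ape` `phylo` object or a newick string.
#' @param pairing named list `A`, `B`, `C`, `D` of chromosome names expected
#'   in each post-2R clade.
#' @param reference_species species whose leaves define the backbone.
#' @param outgroup_species pre-WGD species used to root the tree.
#' @param label_regex passed to [parse_leaf_labels()].
#' @return a `labeled_gene_tree`: list with the rooted `tree`, the `leaves`
#'   table (with `group` and `role` columns), `usable` and `reason`.
#' @export
label_backbone <- function(tree, pairing, reference_species,
                           outgroup_species,
                           label_regex = "^([^|]+)\\|([^|]+)\\|([^|]+)$") {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  leaves <- parse_leaf_labels(tree$tip.label, label_regex)
  leaves$role <- ifelse(leaves$species %in% outgroup_species, "outgroup",
                 ifelse(leaves$species %in% reference_species, "reference",
                        "test"))
  og <- leaves$label[leaves$role == "outgroup"]
  if (!length(og))
    stop("tree has no outgroup leaf; cannot root", call. = FALSE)

  rooted <- tryCatch(
    ape::root(tree, outgroup = og, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(rooted)) {
    return(structure(list(tree = tree, leaves = leaves, usable = FALSE,
                          reason = "outgroup not monophyletic"),
                     class = "labeled_gene_tree"))
  }
  leaves <- leaves[match(rooted$tip.label, leaves$label), , drop = FALSE]
  rownames(leaves) <- NULL

  grp <- rep(NA_character_, nrow(leaves))
  for (x in names(pairing)) {
    grp[leaves$role == "reference" &
          leaves$chromosome %in% pairing[[x]]] <- x
  }
  leaves$group <- grp
  n_groups <- length(unique(stats::na.omit(grp)))
  if (n_groups < 2L) {
    return(structure(list(tree = rooted, leaves = leaves, usable = FALSE,
                          reason = "fewer than 2 backbone groups present"),
                     class = "labeled_gene_tree"))
  }

  ## verify the backbone on reference + outgroup leaves only
  keep <- leaves$label[leaves$role == "outgroup" |
                         (leaves$role == "reference" & !is.na(leaves$group))]
  sub <- ape::keep.tip(rooted, keep)
  mono <- function(tips) length(tips) <= 1L ||
    ape::is.monophyletic(sub, tips)
  ok <- TRUE
  for (x in c("A", "B", "C", "D")) {
    tx <- leaves$label[!is.na(leaves$group) & leaves$group == x]
    if (length(tx) && !mono(tx)) ok <- FALSE
  }
  for (pr in list(c("A", "B"), c("C", "D"))) {
    tx <- leaves$label[!is.na(leaves$group) & leaves$group %in% pr]
    both <- all(pr %in% leaves$group)
    if (both && length(tx) && !mono(tx)) ok <- FALSE
  }
  structure(list(tree = rooted, leaves = leaves, usable = ok,
                 reason = if (ok) NA_character_ else "backbone violates ((A,B),(C,D))"),
            class = "labeled_gene_tree")
}

#' @export
print.labeled_gene_tree <- function(x, ...) {
  cat(sprintf("<labeled_gene_tree> %d leaves, usable: %s%s\n",
              length(x$tree$tip.label), x$usable,
              if (!x$usable) paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

## parent node of `node`, NA at the root
tree_parent <- function(tree, node) {
  i <- match(node, tree$edge[, 2L])
  if (is.na(i)) NA_integer_ else tree$edge[i, 1L]
}

## maximal clades whose tips all belong to `tipset` (tip indices)
maximal_pure_clades <- function(tree, tipset) {
  roots <- integer()
  for (tp in tipset) {
    cur <- tp
    repeat {
      par <- tree_parent(tree, cur)
      if (is.na(par)) break
      tips <- unlist(phangorn::Descendants(tree, par, "tips"))
      if (all(tips %in% tipset)) cur <- par else break
    }
    roots <- c(roots, cur)
  }
  roots <- unique(roots)
  lapply(roots, function(r)
    if (r <= length(tree$tip.label)) r
    else unlist(phangorn::Descendants(tree, r, "tips")))
}

#' Classify test-species genes for shared-WGD compatibility
#'
#' For each maximal clade of test-species leaves, finds where it attaches on
#' the labeled gnathostome backbone.
#' * `supports_2R`: the clade attaches inside, or as sister to, exactly one
#'   of the four post-2R clades A/B/C/D — the position of a lineage sharing
#'   both WGD rounds.
#' * `supports_1R`: `supports_2R`, or attachment as sister to one whole 1R
#'   pair `(A,B)` / `(C,D)` — the position of a lineage diverging after the
#'   first but before the second round.
#' * attachment outside the reference ingroup (sister to all of A-D, or with
#'   the outgroup) supports neither.
#' A polytomy containing the test clade alongside a complete backbone clade
#' is scored as sister to that clade and flagged ambiguous. Branch lengths
#' and support values are ignored: only topology matters.
#'
#' @param lt a usable `labeled_gene_tree` from [label_backbone()].
#' @param test_species character vector of test species.
#' @return data frame: one row per test clade with `species`, `n_tips`,
#'   `supports_1R`, `supports_2R`, `attachment`, `ambiguous`.
#' @export
classify_test_genes <- function(lt, test_species) {
  stopifnot(inherits(lt, "labeled_gene_tree"))
  if (!lt$usable)
    stop("tree flagged unusable: ", lt$reason, call. = FALSE)
  leaves <- lt$leaves
  empty <- data.frame(species = character(), n_tips = integer(),
                      supports_1R = logical(), supports_2R = logical(),
                      attachment = character(), ambiguous = logical(),
                      stringsAsFactors = FALSE)
  test_labels <- leaves$label[leaves$species %in% test_species]
  if (!length(test_labels)) return(empty)

  backbone <- leaves$label[leaves$role == "outgroup" |
                             (leaves$role == "reference" & !is.na(leaves$group))]
  tr0 <- lt$tree
  all_test_tips <- match(test_labels, tr0$tip.label)
  clades <- maximal_pure_clades(tr0, all_test_tips)

  res <- lapply(clades, function(tips) {
    labs <- tr0$tip.label[tips]
    sp <- paste(sort(unique(leaves$species[match(labs, leaves$label)])),
                collapse = "+")
    ## prune to backbone + this clade only, so other test clades cannot mask
    ## the attachment branch
    tr <- ape::keep.tip(tr0, c(backbone, labs))
    ft <- match(labs, tr$tip.label)
    node <- if (length(ft) == 1L) ft else ape::getMRCA(tr, ft)
    par <- tree_parent(tr, node)
    if (is.na(par)) {
      return(data.frame(species = sp, n_tips = length(labs),
                        supports_1R = FALSE, supports_2R = FALSE,
                        attachment = "root", ambiguous = TRUE,
                        stringsAsFactors = FALSE))
    }
    sibs <- setdiff(tr$edge[tr$edge[, 1L] == par, 2L], node)
    sib_tips <- lapply(sibs, function(s)
      tr$tip.label[unlist(phangorn::Descendants(tr, s, "tips"))])
    S <- unlist(sib_tips)
    li <- match(S, leaves$label)
    has_og <- any(leaves$role[li] == "outgroup")
    gs <- unique(stats::na.omit(leaves$group[li]))

    s1 <- FALSE; s2 <- FALSE; ambiguous <- FALSE
    attachment <- "outside"
    if (!has_og && length(gs)) {
      if (length(gs) == 1L) {
        s2 <- TRUE; s1 <- TRUE
        attachment <- paste0("within_or_sister:", gs)
      } else if (setequal(gs, c("A", "B"))) {
        s1 <- TRUE; attachment <- "sister_pair:AB"
      } else if (setequal(gs, c("C", "D"))) {
        s1 <- TRUE; attachment <- "sister_pair:CD"
      }
    }
    if (!s1 && length(sibs) > 1L) {
      ## permissive polytomy reading: a complete backbone clade beside the
      ## test clade counts as its sister
      for (st in sib_tips) {
        g <- unique(stats::na.omit(leaves$group[match(st, leaves$label)]))
        og_in <- any(leaves$role[match(st, leaves$label)] == "outgroup")
        if (og_in) next
        if (length(g) == 1L) {
          s2 <- TRUE; s1 <- TRUE; ambiguous <- TRUE
          attachment <- paste0("polytomy_sister:", g)
          break
        }
        if (setequal(g, c("A", "B")) || setequal(g, c("C", "D"))) {
          s1 <- TRUE; ambiguous <- TRUE
          attachment <- paste0("polytomy_sister_pair:",
                               paste(g, collapse = ""))
          break
        }
      }
    }
    data.frame(species = sp, n_tips = length(labs), supports_1R = s1,
               supports_2R = s2, attachment = attachment,
               ambiguous = ambiguous, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$species, out$attachment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-tree conservative compatibility call
#'
#' A tree supports a WGD round only if *all* its test clades do (the
#' conservative conjunction used for per-tree tallies).
#'
#' @param calls output of [classify_test_genes()] for one tree.
#' @return list `supports_1R`, `supports_2R` (logical).
#' @export
tree_call <- function(calls) {
  list(supports_1R = nrow(calls) > 0 && all(calls$supports_1R),
       supports_2R = nrow(calls) > 0 && all(calls$supports_2R))
}

#' Tally compatibility support fractions per test species
#'
#' @param calls data frame of compatibility calls (rows from
#'   [classify_test_genes()] across trees, or per-tree calls with a
#'   `species` column).
#' @return data frame `species`, `n`, `frac_1R`, `frac_2R`, sorted by
#'   species.
#' @export
tally_support <- function(calls) {
  if (!nrow(calls))
    return(data.frame(species = character(), n = integer(),
                      frac_1R = numeric(), frac_2R = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(calls, calls$species), function(dd)
    data.frame(species = dd$species[1L], n = nrow(dd),
               frac_1R = mean(dd$supports_1R),
               frac_2R = mean(dd$supports_2R), stringsAsFactors = FALSE)))
  out <- out[order(out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}
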