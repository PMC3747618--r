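#' Logic trees: Boolean interaction models over binary SNPs
#'
#' A logic tree is a rooted, strictly binary tree whose leaves are SNP
#' literals (a SNP or its negation) and whose internal nodes carry the
#' operators AND / OR. A tree represents one Boolean interaction among SNPs:
#' `(X1 & X2) & (!X3 | X4)` is true for an individual iff SNPs 1 and 2 carry
#' the mutant allele and SNP 3 is wild type or SNP 4 is mutant. Negation
#' lives only on leaves; internal nodes are never negated.
#'
#' Internally a tree is a nested list: a leaf is `list(snp =, neg =)` and an
#' internal node is `list(op = "and"|"or", left =, right =)`. The root
#' carries class `"logic_tree"`.
#'
#' @param snp 1-based SNP (column) index.
#' @param neg logical; `TRUE` for the negated literal `!Xj`.
#' @return `lt_leaf()` returns a leaf node, `lt_node()` an internal node;
#'   both are valid `logic_tree` objects.
#' @examples
#' tr <- lt_node("and", lt_leaf(1), lt_node("or", lt_leaf(3, neg = TRUE), lt_leaf(4)))
#' format(tr)
#' @name logic_tree
NULL

new_logic_tree <- function(x) {
  class(x) <- "logic_tree"
  x
}

#' @rdname logic_tree
#' @export
lt_leaf <- function(snp, neg = FALSE) {
  stopifnot(is.numeric(snp), length(snp) == 1L, snp >= 1, is.logical(neg))
  new_logic_tree(list(snp = as.integer(snp), neg = neg))
}

#' @rdname logic_tree
#' @param op operator, `"and"` or `"or"`.
#' @param left,right child subtrees (leaves or internal nodes).
#' @export
lt_node <- function(op, left, right) {
  op <- match.arg(op, c("and", "or"))
  new_logic_tree(list(op = op, left = left, right = right))
}

is_leaf <- function(node) !is.null(node$snp)

#' @export
print.logic_tree <- function(x, ...) {
  cat("<logic_tree> ", format(x), "  [size ", tree_size(x), "]\n", sep = "")
  invisible(x)
}

#' Tree structure accessors
#'
#' `tree_size()` counts leaves (the tree size \eqn{s_i}); `tree_snps()`
#' returns the leaf SNP indices in left-to-right order (with repeats, if
#' any); `snp_indicator()` returns the binary indicator vector
#' \eqn{\vec{q}_i} of length `n_snps` whose j-th entry is 1 iff SNP j occurs
#' as a leaf.
#'
#' @param tree a `logic_tree`.
#' @param n_snps total number of SNP columns N.
#' @return An integer scalar, integer vector, or 0/1 integer vector.
#' @export
tree_size <- function(tree) {
  if (is_leaf(tree)) 1L else tree_size(tree$left) + tree_size(tree$right)
}

#' @rdname tree_size
#' @export
tree_snps <- function(tree) {
  if (is_leaf(tree)) tree$snp else c(tree_snps(tree$left), tree_snps(tree$right))
}

#' @rdname tree_size
#' @export
snp_indicator <- function(tree, n_snps) {
  q <- integer(n_snps)
  q[unique(tree_snps(tree))] <- 1L
  q
}

n_internal <- function(tree) tree_size(tree) - 1L

count_ops <- function(tree, op) {
  if (is_leaf(tree)) return(0L)
  (tree$op == op) + count_ops(tree$left, op) + count_ops(tree$right, op)
}

#' Evaluate a logic tree on binary genotypes
#'
#' Computes the Boolean value of the tree for one genotype vector
#' (`eval_tree()`) or for every row of a binary genotype matrix
#' (`eval_tree_rows()`). A negated literal `!Xj` evaluates to `1 - allele`.
#'
#' @param tree a `logic_tree`.
#' @param genotype binary (0/1) vector of length at least the largest leaf
#'   index.
#' @param genotypes binary matrix, one row per individual.
#' @return 0/1 integer scalar, or an integer vector with one entry per row.
#' @examples
#' tr <- parse_tree("X1 & X2 & (!X3 | X4)")
#' eval_tree(tr, c(1, 1, 0, 0)) # 1
#' eval_tree(tr, c(0, 1, 1, 1)) # 0
#' @export
eval_tree <- function(tree, genotype) {
  if (max(tree_snps(tree)) > length(genotype)) {
    stop("leaf SNP index exceeds genotype length", call. = FALSE)
  }
  eval_tree_rows(tree, rbind(genotype))
}

#' @rdname eval_tree
#' @export
eval_tree_rows <- function(tree, genotypes) {
  if (max(tree_snps(tree)) > ncol(genotypes)) {
    stop("leaf SNP index exceeds number of genotype columns", call. = FALSE)
  }
  if (!is.integer(genotypes)) storage.mode(genotypes) <- "integer"
  .eval_tree_c(genotypes, tree, seq_len(nrow(genotypes)) - 1L)
}

## pure-R reference evaluator (kept as an internal cross-check)
eval_rec <- function(node, X) {
  if (is_leaf(node)) {
    v <- X[, node$snp]
    if (node$neg) 1L - v else v
  } else if (node$op == "and") {
    eval_rec(node$left, X) * eval_rec(node$right, X)
  } else {
    pmax(eval_rec(node$left, X), eval_rec(node$right, X))
  }
}

## ---- fast single-pass tree editors ----------------------------------------
## These walk the tree once, touching the k-th leaf (or internal node) in
## left-to-right order. `fun(leaf)` returns the replacement subtree, or
## NULL to delete the leaf (its sibling is promoted).

edit_nth_leaf <- function(tree, k, fun) {
  cnt <- 0L
  rec <- function(node) {
    if (is_leaf(node)) {
      cnt <<- cnt + 1L
      if (cnt == k) return(fun(node))
      return(node)
    }
    l <- rec(node$left)
    if (cnt >= k) {
      if (is.null(l)) return(node$right)
      node$left <- l
      return(node)
    }
    r <- rec(node$right)
    if (is.null(r)) return(node$left)
    node$right <- r
    node
  }
  out <- rec(tree)
  if (is.null(out)) return(NULL)
  new_logic_tree(out)
}

edit_nth_internal <- function(tree, k, fun) {
  cnt <- 0L
  rec <- function(node) {
    if (is_leaf(node)) return(node)
    cnt <<- cnt + 1L
    if (cnt == k) return(fun(node))
    node$left <- rec(node$left)
    if (cnt < k) node$right <- rec(node$right)
    node
  }
  new_logic_tree(rec(tree))
}

## ---- tree-editing moves ----------------------------------------------------

#' The four tree-editing moves
#'
#' `apply_move()` performs one of the elementary edits used by the search:
#' * `ADD_SNP` attaches a fresh literal at a uniformly chosen leaf position,
#'   under a new AND/OR parent (size +1);
#' * `DEL_SNP` removes one leaf and its parent operator, promoting the
#'   sibling (size -1);
#' * `ALT_SNP` replaces one leaf's literal by a different literal (size
#'   unchanged; the identical literal is never redrawn);
#' * `ALT_OPT` flips one internal node between AND and OR (size unchanged).
#'
#' Leaf and operator positions are chosen uniformly unless weights are
#' given; SNPs for new/replacement literals are drawn from `snp_probs`
#' (uniform over `1:n_snps` by default). Infeasible moves (`DEL_SNP` on a
#' single leaf, `ALT_OPT` with no internal node) signal a condition of class
#' `swarmlr_infeasible_move` so callers can resample a behavior.
#'
#' @param tree a `logic_tree`.
#' @param move one of `"ADD_SNP"`, `"DEL_SNP"`, `"ALT_SNP"`, `"ALT_OPT"`.
#' @param n_snps number of SNP columns available.
#' @param snp_probs optional probability weights over `1:n_snps` for the
#'   added / replacement SNP.
#' @param leaf_weights optional weights over the tree's leaves (in
#'   left-to-right order) for choosing the victim leaf of `DEL_SNP` /
#'   `ALT_SNP`.
#' @param allow_negation may new / replacement literals be negated?
#' @return The edited `logic_tree`.
#' @examples
#' set.seed(1)
#' apply_move(lt_leaf(1), "ADD_SNP", n_snps = 5)
#' @export
apply_move <- function(tree, move = c("ADD_SNP", "DEL_SNP", "ALT_SNP", "ALT_OPT"),
                       n_snps, snp_probs = NULL, leaf_weights = NULL,
                       allow_negation = TRUE) {
  move <- match.arg(move)
  if (!move_feasible(tree, move)) {
    stop(structure(
      class = c("swarmlr_infeasible_move", "error", "condition"),
      list(message = paste0("move ", move, " infeasible on tree of size ",
                            tree_size(tree)),
           call = sys.call())))
  }
  switch(move,
    ADD_SNP = move_add(tree, n_snps, snp_probs, allow_negation),
    DEL_SNP = move_del(tree, leaf_weights),
    ALT_SNP = move_alt_snp(tree, n_snps, snp_probs, leaf_weights, allow_negation),
    ALT_OPT = move_alt_opt(tree))
}

#' @rdname apply_move
#' @export
move_feasible <- function(tree, move) {
  switch(move,
    ADD_SNP = TRUE,
    DEL_SNP = tree_size(tree) >= 2L,
    ALT_SNP = TRUE,
    ALT_OPT = tree_size(tree) >= 2L,
    stop("unknown move: ", move, call. = FALSE))
}

draw_literal <- function(n_snps, snp_probs, allow_negation, forbid = NULL) {
  for (i in 1:100) {
    snp <- sample_idx(n_snps, snp_probs)
    neg <- allow_negation && stats::runif(1) < 0.5
    if (is.null(forbid) || snp != forbid$snp || neg != forbid$neg) {
      return(list(snp = snp, neg = neg))
    }
  }
  # only reachable when a single literal has all the probability mass
  if (allow_negation) return(list(snp = forbid$snp, neg = !forbid$neg))
  stop("cannot draw a literal different from the current one", call. = FALSE)
}

sample_idx <- function(n, probs = NULL) {
  if (!is.null(probs)) {
    if (length(probs) != n) stop("probability vector has wrong length", call. = FALSE)
    if (all(probs <= 0)) probs <- rep(1, n)
  }
  sample.int(n, 1L, prob = probs)
}

move_add <- function(tree, n_snps, snp_probs, allow_negation) {
  k <- sample_idx(tree_size(tree))
  lit <- draw_literal(n_snps, snp_probs, allow_negation)
  op <- if (stats::runif(1) < 0.5) "and" else "or"
  left_new <- stats::runif(1) < 0.5
  edit_nth_leaf(tree, k, function(leaf) {
    if (left_new) list(op = op, left = lit, right = leaf)
    else list(op = op, left = leaf, right = lit)
  })
}

move_del <- function(tree, leaf_weights) {
  k <- sample_idx(tree_size(tree), leaf_weights)
  edit_nth_leaf(tree, k, function(leaf) NULL)
}

move_alt_snp <- function(tree, n_snps, snp_probs, leaf_weights, allow_negation) {
  k <- sample_idx(tree_size(tree), leaf_weights)
  edit_nth_leaf(tree, k, function(leaf) {
    draw_literal(n_snps, snp_probs, allow_negation, forbid = leaf)
  })
}

move_alt_opt <- function(tree) {
  k <- sample_idx(tree_size(tree) - 1L)
  edit_nth_internal(tree, k, function(node) {
    node$op <- if (node$op == "and") "or" else "and"
    node
  })
}

## Remove every leaf whose SNP is in `snps`; NULL if the tree empties.
prune_snps <- function(tree, snps) {
  if (is_leaf(tree)) {
    if (tree$snp %in% snps) return(NULL)
    return(tree)
  }
  l <- prune_snps(tree$left, snps)
  r <- prune_snps(tree$right, snps)
  if (is.null(l) && is.null(r)) return(NULL)
  if (is.null(l)) return(new_logic_tree(r))
  if (is.null(r)) return(new_logic_tree(l))
  tree$left <- l
  tree$right <- r
  tree
}

#' Random logic tree
#'
#' Draws a uniformly shaped binary tree with `size` leaves, SNPs sampled
#' from `snp_probs` (uniform by default) and AND/OR drawn uniformly at each
#' internal node. Used for swarm initialization and for planting causal
#' expressions.
#'
#' @param n_snps number of SNP columns.
#' @param size number of leaves.
#' @param snps optional fixed leaf multiset: exactly these SNP indices are
#'   used as leaves (in random order); overrides `size`.
#' @param op operator policy for internal nodes: `"random"` (uniform
#'   AND/OR per node), `"and"`, or `"or"`.
#' @inheritParams apply_move
#' @return A `logic_tree`.
#' @export
random_tree <- function(n_snps, size = 1L, snp_probs = NULL,
                        allow_negation = TRUE, snps = NULL, op = "random") {
  op <- match.arg(op, c("random", "and", "or"))
  if (is.null(snps)) {
    snps <- vapply(seq_len(size), function(i) sample_idx(n_snps, snp_probs), 1L)
  } else {
    snps <- sample(as.integer(snps))
  }
  negs <- if (allow_negation) stats::runif(length(snps)) < 0.5 else rep(FALSE, length(snps))
  draw_op <- function() if (op == "random") sample(c("and", "or"), 1L) else op
  build <- function(idx) {
    if (length(idx) == 1L) return(lt_leaf(snps[idx], negs[idx]))
    cut <- if (length(idx) == 2L) 1L else sample.int(length(idx) - 1L, 1L)
    lt_node(draw_op(), build(idx[seq_len(cut)]), build(idx[-seq_len(cut)]))
  }
  build(seq_along(snps))
}

## ---- OR-split forest and the solution-space embedding ----------------------

#' Split a logic tree into its AND-only forest
#'
#' Recursively distributes AND over OR until the tree is a disjunction of
#' pure conjunctions: the forest of "sub-logic-trees". Each conjunction is
#' returned as a sorted set of signed SNP indices (`+j` for `Xj`, `-j` for
#' `!Xj`); the OR over the conjunctions evaluates identically to the source
#' tree on every binary input. Duplicate literals inside a conjunction are
#' collapsed and duplicate conjunctions removed (absorption is not applied).
#'
#' @param tree a `logic_tree`.
#' @return An object of class `lt_forest`: a list of signed-integer
#'   conjunctions.
#' @examples
#' split_to_forest(parse_tree("X1 & X2 & (!X3 | X4)"))
#' @export
split_to_forest <- function(tree) {
  conj <- forest_rec(tree)
  keys <- vapply(conj, function(cc) paste(cc, collapse = ","), "")
  conj <- conj[!duplicated(keys)]
  structure(conj, class = "lt_forest")
}

forest_rec <- function(node) {
  if (is_leaf(node)) {
    return(list(if (node$neg) -node$snp else node$snp))
  }
  l <- forest_rec(node$left)
  r <- forest_rec(node$right)
  if (node$op == "or") return(c(l, r))
  out <- vector("list", length(l) * length(r))
  k <- 0L
  for (a in l) for (b in r) {
    k <- k + 1L
    out[[k]] <- sort(unique(c(a, b)))
  }
  out
}

#' @export
print.lt_forest <- function(x, ...) {
  lits <- vapply(x, function(cc) {
    paste(ifelse(cc < 0, paste0("!X", -cc), paste0("X", cc)), collapse = " & ")
  }, "")
  cat("<lt_forest> ", length(x), " conjunction(s):\n", sep = "")
  cat(paste0("  {", lits, "}"), sep = "\n")
  invisible(x)
}

#' Evaluate a forest (OR of conjunctions) on genotype rows
#' @param forest an `lt_forest`.
#' @param genotypes binary matrix.
#' @return 0/1 integer vector, one entry per row.
#' @export
eval_forest_rows <- function(forest, genotypes) {
  out <- integer(nrow(genotypes))
  for (cc in forest) {
    v <- rep(1L, nrow(genotypes))
    for (lit in cc) {
      col <- genotypes[, abs(lit)]
      v <- v * (if (lit < 0) 1L - col else col)
    }
    out <- pmax(out, v)
  }
  out
}

#' Solution-space coordinate of a logic tree
#'
#' Embeds a tree into the search hyperspace used for swarm communication:
#' the number of AND-only sub-trees `n` after OR-splitting, their sizes
#' (or, in simplified mode, the scalar size of the original tree), and the
#' tree's score `Y`.
#'
#' @param tree a `logic_tree`.
#' @param score the tree's score (already computed).
#' @param simplified replace the size vector by the scalar size of the
#'   original tree.
#' @return A list with elements `n`, `sizes`, `score`.
#' @export
tree_coordinate <- function(tree, score, simplified = FALSE) {
  forest <- split_to_forest(tree)
  sizes <- if (simplified) tree_size(tree) else lengths(forest)
  list(n = length(forest), sizes = as.integer(sizes), score = score)
}

## ---- serialization ---------------------------------------------------------

#' @export
format.logic_tree <- function(x, ...) fmt_rec(x, top = TRUE)

fmt_rec <- function(node, top = FALSE) {
  if (is_leaf(node)) {
    return(paste0(if (node$neg) "!" else "", "X", node$snp))
  }
  sym <- if (node$op == "and") "&" else "|"
  l <- fmt_rec(node$left)
  r <- fmt_rec(node$right)
  if (!is_leaf(node$left)) l <- paste0("(", l, ")")
  if (!is_leaf(node$right)) r <- paste0("(", r, ")")
  paste(l, sym, r)
}

#' @export
as.character.logic_tree <- function(x, ...) format(x)

#' Parse a logic tree from infix text
#'
#' Reads expressions such as `"(X1 & X2) & (!X3 | X4)"`. `!` binds tighter
#' than `&`, which binds tighter than `|`; same-operator chains associate to
#' the left, keeping the tree strictly binary. Negation is only accepted on
#' literals.
#'
#' @param text a single string.
#' @return A `logic_tree`; `format()` of the result round-trips.
#' @export
parse_tree <- function(text) {
  toks <- regmatches(text, gregexpr("X[0-9]+|[!&|()]", text))[[1]]
  if (sum(nchar(gsub("[[:space:]]", "", text))) != sum(nchar(toks))) {
    stop("unparseable characters in tree text: ", text, call. = FALSE)
  }
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_or <- function() {
    node <- parse_and()
    while (peek() == "|") { take(); node <- lt_node("or", node, parse_and()) }
    node
  }
  parse_and <- function() {
    node <- parse_atom()
    while (peek() == "&") { take(); node <- lt_node("and", node, parse_atom()) }
    node
  }
  parse_atom <- function() {
    t <- take()
    if (t == "(") {
      node <- parse_or()
      if (take() != ")") stop("expected ')'", call. = FALSE)
      return(node)
    }
    if (t == "!") {
      inner <- parse_atom()
      if (!is_leaf(inner)) stop("negation is only allowed on leaves", call. = FALSE)
      inner$neg <- !inner$neg
      return(inner)
    }
    if (grepl("^X[0-9]+$", t)) return(lt_leaf(as.integer(sub("X", "", t))))
    stop("unexpected token '", t, "'", call. = FALSE)
  }
  out <- parse_or()
  if (peek() != "") stop("trailing tokens after expression", call. = FALSE)
  new_logic_tree(out)
}

#' JSON serialization of logic trees
#'
#' `tree_to_json()` writes a tree as a JSON document with explicit node
#' records (`type`, `snp`, `neg`, `children`); `tree_from_json()` reads it
#' back. Round-trips exactly.
#'
#' @param tree a `logic_tree`.
#' @param json a JSON string produced by `tree_to_json()`.
#' @return A JSON string / a `logic_tree`.
#' @export
tree_to_json <- function(tree) {
  jsonlite::toJSON(tree_to_record(tree), auto_unbox = TRUE)
}

tree_to_record <- function(node) {
  if (is_leaf(node)) {
    list(type = "leaf", snp = node$snp, neg = node$neg)
  } else {
    list(type = node$op,
         children = list(tree_to_record(node$left), tree_to_record(node$right)))
  }
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(json) {
  rec_to_tree(jsonlite::fromJSON(json, simplifyVector = FALSE))
}

rec_to_tree <- function(rec) {
  if (rec$type == "leaf") return(lt_leaf(rec$snp, isTRUE(rec$neg)))
  lt_node(rec$type, rec_to_tree(rec$children[[1]]), rec_to_tree(rec$children[[2]]))
}
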