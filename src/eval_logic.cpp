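#include <Rcpp.h>
using namespace Rcpp;

// Logic-tree nodes arrive as nested R lists: a leaf is list(snp, neg)
// (length 2), an internal node list(op, left, right) (length 3, op "and"
// or "or"). Evaluation is vectorized per node over a row subset so that
// genotype columns are read sequentially (column-major friendly).
static void eval_node(SEXP node, const int* X, const int m,
                      const int* rows, const int nr, int* out) {
  if (Rf_xlength(node) == 2) {          // leaf: (snp, neg)
    const int snp = Rf_asInteger(VECTOR_ELT(node, 0));
    const bool neg = Rf_asLogical(VECTOR_ELT(node, 1));
    const int* col = X + (size_t)(snp - 1) * m;
    if (neg) {
      for (int i = 0; i < nr; ++i) out[i] = 1 - col[rows[i]];
    } else {
      for (int i = 0; i < nr; ++i) out[i] = col[rows[i]];
    }
    return;
  }
  eval_node(VECTOR_ELT(node, 1), X, m, rows, nr, out);
  std::vector<int> tmp(nr);
  eval_node(VECTOR_ELT(node, 2), X, m, rows, nr, tmp.data());
  const char* op = CHAR(STRING_ELT(VECTOR_ELT(node, 0), 0));
  if (op[0] == 'a') {
    for (int i = 0; i < nr; ++i) out[i] &= tmp[i];
  } else {
    for (int i = 0; i < nr; ++i) out[i] |= tmp[i];
  }
}

// Tree outputs on a 0-based row subset of the binary genotype matrix.
// [[Rcpp::export(name = ".eval_tree_c")]]
IntegerVector eval_tree_c(const IntegerMatrix& X, const List& tree,
                          const IntegerVector& rows) {
  const int nr = rows.size();
  IntegerVector out(nr);
  eval_node(tree, X.begin(), X.nrow(), rows.begin(), nr, out.begin());
  return out;
}

// Sufficient statistics of a tree against the phenotype on a weighted row
// subset: (weighted matches, weighted sum of outputs, weighted sum of
// output * y). `rows` are 0-based; `w` their multiplicities.
// [[Rcpp::export(name = ".score_tree_c")]]
NumericVector score_tree_c(const IntegerMatrix& X, const List& tree,
                           const IntegerVector& rows, const NumericVector& w,
                           const IntegerVector& y) {
  const int nr = rows.size();
  std::vector<int> out(nr);
  eval_node(tree, X.begin(), X.nrow(), rows.begin(), nr, out.data());
  double matches = 0, sum_out = 0, sum_outy = 0;
  for (int i = 0; i < nr; ++i) {
    const int v = out[i], yr = y[rows[i]];
    matches += w[i] * (v == yr);
    sum_out += w[i] * v;
    sum_outy += w[i] * (v & yr);
  }
  return NumericVector::create(matches, sum_out, sum_outy);
}
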