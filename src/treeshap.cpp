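// Exact path-dependent TreeSHAP in double precision for boosted regression
// trees, plus the conditioned variant needed for pairwise Shapley interaction
// values. Trees arrive as flat arrays parsed from the booster text dump; leaf
// weights ("cover") define the conditional expectations, so attributions here
// reproduce the classic polynomial-time tree Shapley recursion without the
// float32 round-off of the booster's built-in contribution predictor.
#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

namespace {

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

struct Tree {
  const int *left, *right, *missing, *feature;
  const double *threshold, *value, *cover;
  int n_nodes;
  int max_depth;
};

void extend_path(PathElement *unique_path, int unique_depth,
                 double zero_fraction, double one_fraction,
                 int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  for (int i = unique_depth - 1; i >= 0; --i) {
    unique_path[i + 1].pweight +=
        one_fraction * unique_path[i].pweight * (i + 1) / (double)(unique_depth + 1);
    unique_path[i].pweight =
        zero_fraction * unique_path[i].pweight * (unique_depth - i) / (double)(unique_depth + 1);
  }
}

void unwind_path(PathElement *unique_path, int unique_depth, int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight =
          next_one_portion * (unique_depth + 1) / (double)((i + 1) * one_fraction);
      next_one_portion =
          tmp - unique_path[i].pweight * zero_fraction * (unique_depth - i) /
                    (double)(unique_depth + 1);
    } else {
      unique_path[i].pweight = (unique_path[i].pweight * (unique_depth + 1)) /
                               (double)(zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

double unwound_path_sum(const PathElement *unique_path, int unique_depth,
                        int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp =
          next_one_portion * (unique_depth + 1) / (double)((i + 1) * one_fraction);
      total += tmp;
      next_one_portion =
          unique_path[i].pweight -
          tmp * zero_fraction * ((unique_depth - i) / (double)(unique_depth + 1));
    } else if (zero_fraction != 0) {
      total += (unique_path[i].pweight / zero_fraction) /
               ((unique_depth - i) / (double)(unique_depth + 1));
    }
  }
  return total;
}

// condition: 0 none; +1 feature fixed present; -1 feature fixed absent.
void tree_shap_recursive(const Tree &tree, const double *x, double *phi,
                         int node_index, int unique_depth,
                         PathElement *parent_unique_path,
                         double parent_zero_fraction,
                         double parent_one_fraction, int parent_feature_index,
                         int condition, int condition_feature,
                         double condition_fraction) {
  if (condition_fraction == 0) return;

  PathElement *unique_path = parent_unique_path + unique_depth + 1;
  std::memcpy(unique_path, parent_unique_path,
              (unique_depth + 1) * sizeof(PathElement));

  if (condition == 0 || condition_feature != parent_feature_index) {
    extend_path(unique_path, unique_depth, parent_zero_fraction,
                parent_one_fraction, parent_feature_index);
  }
  const int split_index = tree.feature[node_index];

  if (tree.left[node_index] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      phi[el.feature_index] += w * (el.one_fraction - el.zero_fraction) *
                               tree.value[node_index] * condition_fraction;
    }
    return;
  }

  int hot_index;
  const double xv = x[split_index];
  if (ISNAN(xv)) {
    hot_index = tree.missing[node_index];
  } else if ((float)xv < (float)tree.threshold[node_index]) {
    // float casts reproduce the booster's single-precision split decisions
    hot_index = tree.left[node_index];
  } else {
    hot_index = tree.right[node_index];
  }
  const int cold_index = (hot_index == tree.left[node_index]
                              ? tree.right[node_index]
                              : tree.left[node_index]);
  const double w = tree.cover[node_index];
  const double hot_zero_fraction = tree.cover[hot_index] / w;
  const double cold_zero_fraction = tree.cover[cold_index] / w;
  double incoming_zero_fraction = 1;
  double incoming_one_fraction = 1;

  // undo any earlier split on this feature so it can be redone here
  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (unique_path[path_index].feature_index == split_index) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  double hot_condition_fraction = condition_fraction;
  double cold_condition_fraction = condition_fraction;
  if (condition > 0 && split_index == condition_feature) {
    cold_condition_fraction = 0;
    unique_depth -= 1;
  } else if (condition < 0 && split_index == condition_feature) {
    hot_condition_fraction *= hot_zero_fraction;
    cold_condition_fraction *= cold_zero_fraction;
    unique_depth -= 1;
  }

  tree_shap_recursive(tree, x, phi, hot_index, unique_depth + 1, unique_path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_index, condition,
                      condition_feature, hot_condition_fraction);
  tree_shap_recursive(tree, x, phi, cold_index, unique_depth + 1, unique_path,
                      cold_zero_fraction * incoming_zero_fraction, 0,
                      split_index, condition, condition_feature,
                      cold_condition_fraction);
}

double tree_expected_value(const Tree &tree, int node) {
  if (tree.left[node] < 0) return tree.value[node];
  const int l = tree.left[node], r = tree.right[node];
  return (tree.cover[l] * tree_expected_value(tree, l) +
          tree.cover[r] * tree_expected_value(tree, r)) /
         tree.cover[node];
}

std::vector<Tree> unpack_trees(const List &trees) {
  const IntegerVector left = trees["left"], right = trees["right"],
                      missing = trees["missing"], feature = trees["feature"],
                      offset = trees["offset"], n_nodes = trees["n_nodes"],
                      max_depth = trees["max_depth"];
  const NumericVector threshold = trees["threshold"], value = trees["value"],
                      cover = trees["cover"];
  const int n_trees = offset.size();
  std::vector<Tree> out(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    const int off = offset[t];
    out[t].left = &left[0] + off;
    out[t].right = &right[0] + off;
    out[t].missing = &missing[0] + off;
    out[t].feature = &feature[0] + off;
    out[t].threshold = &threshold[0] + off;
    out[t].value = &value[0] + off;
    out[t].cover = &cover[0] + off;
    out[t].n_nodes = n_nodes[t];
    out[t].max_depth = max_depth[t];
  }
  return out;
}

// phi has length p+1 (last = bias); computes attributions for one sample
// under an optional condition on one feature.
void shap_one_sample(const std::vector<Tree> &trees, const double *x, int p,
                     double base_score, double *phi, int condition,
                     int condition_feature,
                     std::vector<PathElement> &scratch) {
  std::fill(phi, phi + p + 1, 0.0);
  for (size_t t = 0; t < trees.size(); ++t) {
    const Tree &tr = trees[t];
    const int maxd = tr.max_depth + 2;
    const size_t need = (size_t)maxd * (maxd + 1) / 2 + maxd;
    if (scratch.size() < need) scratch.resize(need);
    if (condition == 0) {
      phi[p] += tree_expected_value(tr, 0);
    }
    tree_shap_recursive(tr, x, phi, 0, 0, scratch.data(), 1.0, 1.0, -1,
                        condition, condition_feature, 1.0);
  }
  if (condition == 0) phi[p] += base_score;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_tree_shap(List trees, NumericMatrix X, double base_score) {
  const std::vector<Tree> tv = unpack_trees(trees);
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix out(n, p + 1);
  std::vector<double> xrow(p), phi(p + 1);
  std::vector<PathElement> scratch;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    shap_one_sample(tv, xrow.data(), p, base_score, phi.data(), 0, -1, scratch);
    for (int j = 0; j <= p; ++j) out(i, j) = phi[j];
  }
  return out;
}

// [[Rcpp::export]]
double cpp_tree_expected(List trees, double base_score) {
  const std::vector<Tree> tv = unpack_trees(trees);
  double s = base_score;
  for (size_t t = 0; t < tv.size(); ++t) s += tree_expected_value(tv[t], 0);
  return s;
}

// Double-precision evaluation of the parsed ensemble (reference for the
// local-additivity identity base + sum(phi) = f(x)).
// [[Rcpp::export]]
NumericVector cpp_predict_trees(List trees, NumericMatrix X, double base_score) {
  const std::vector<Tree> tv = unpack_trees(trees);
  const int n = X.nrow();
  NumericVector out(n, base_score);
  for (int i = 0; i < n; ++i) {
    for (size_t t = 0; t < tv.size(); ++t) {
      const Tree &tr = tv[t];
      int node = 0;
      while (tr.left[node] >= 0) {
        const double xv = X(i, tr.feature[node]);
        if (ISNAN(xv)) node = tr.missing[node];
        else node = ((float)xv < (float)tr.threshold[node])
                        ? tr.left[node] : tr.right[node];
      }
      out[i] += tr.value[node];
    }
  }
  return out;
}

// Pairwise Shapley interaction values. Returns the (p+1)x(p+1) matrix of
// mean absolute values over samples, and optionally the full per-sample
// array (kept only for small n; it is O(n p^2) memory).
// [[Rcpp::export]]
List cpp_tree_shap_interactions(List trees, NumericMatrix X, double base_score,
                                bool per_sample) {
  const std::vector<Tree> tv = unpack_trees(trees);
  const int n = X.nrow(), p = X.ncol(), m = p + 1;

  // features actually used by any split; others have identically zero rows
  std::vector<bool> used(p, false);
  for (size_t t = 0; t < tv.size(); ++t)
    for (int k = 0; k < tv[t].n_nodes; ++k)
      if (tv[t].left[k] >= 0) used[tv[t].feature[k]] = true;

  NumericMatrix mean_abs(m, m);
  NumericVector full;
  if (per_sample) {
    full = NumericVector(Dimension(n, m, m));
  }
  std::vector<double> xrow(p), phi(m), on(m), off(m), row(m);
  std::vector<PathElement> scratch;

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    shap_one_sample(tv, xrow.data(), p, base_score, phi.data(), 0, -1, scratch);
    std::vector<double> diag(phi);  // start from main effects, subtract rows
    for (int f = 0; f <= p; ++f) {
      if (f < p && !used[f]) continue;
      shap_one_sample(tv, xrow.data(), p, base_score, on.data(), 1, f, scratch);
      shap_one_sample(tv, xrow.data(), p, base_score, off.data(), -1, f, scratch);
      for (int j = 0; j <= p; ++j) row[j] = (on[j] - off[j]) / 2.0;
      row[f] = 0.0;
      double rowsum = 0;
      for (int j = 0; j <= p; ++j) rowsum += row[j];
      diag[f] = phi[f] - rowsum;
      for (int j = 0; j <= p; ++j) {
        if (j == f) continue;
        mean_abs(f, j) += std::abs(row[j]) / n;
        if (per_sample) full[i + (size_t)n * f + (size_t)n * m * j] = row[j];
      }
    }
    for (int f = 0; f <= p; ++f) {
      mean_abs(f, f) += std::abs(diag[f]) / n;
      if (per_sample) full[i + (size_t)n * f + (size_t)n * m * f] = diag[f];
    }
  }
  List out = List::create(Named("mean_abs") = mean_abs);
  if (per_sample) out["per_sample"] = full;
  return out;
}
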