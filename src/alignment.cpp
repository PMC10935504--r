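#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Shared kernel for the two alignment passes and graph construction.
//
// rows:    2m integer vectors, bases encoded A,C,G,T,N = 0..4
// weights: 2m numeric vectors, the per-start-position weight entering
//          f' = f * (w_a[j] + w_b[q])  (coverage, neighborhood support,
//          or the combined second-stage matrix, depending on the stage)
// seqidx:  original peak index per row; rows of the same peak are never
//          compared (no self or self-revcomp alignment)
// fk:      f(k) lookup, length l+1; f is the -log10 upper-tail binomial
// kmin:    smallest identity count k with f(k) > threshold (l+1 = never)
// topk:    rank cutoff (alpha for the passes, beta for edges); ties at the
//          cutoff value are all kept; zero-score pairs never rank
// emit_edges: false -> return per-row increment counts (M1/M2 style);
//             true  -> return the qualifying segment pairs as an edge list

// [[Rcpp::export]]
List cpp_all_pairs(List rows, List weights, IntegerVector seqidx, int l,
                   NumericVector fk, int kmin, int topk, bool emit_edges) {
  const int nrow = rows.size();
  std::vector<IntegerVector> R(nrow);
  std::vector<NumericVector> W(nrow);
  std::vector<int> nvalid(nrow);
  for (int i = 0; i < nrow; ++i) {
    R[i] = rows[i];
    W[i] = weights[i];
    nvalid[i] = (int)R[i].size() - l + 1;
    if (nvalid[i] < 1) stop("segment length l exceeds a sequence length");
  }

  List counts(nrow);
  std::vector<IntegerVector> C(nrow);
  if (!emit_edges) {
    for (int i = 0; i < nrow; ++i) {
      C[i] = IntegerVector(nvalid[i]);
      counts[i] = C[i];
    }
  }
  std::vector<int> e_row_a, e_pos_a, e_row_b, e_pos_b;
  std::vector<double> e_w;

  std::vector<signed char> kmat;
  std::vector<double> fpmat, pos_fp;

  for (int a = 0; a < nrow; ++a) {
    for (int b = a + 1; b < nrow; ++b) {
      if (seqidx[a] == seqidx[b]) continue;
      const int nA = R[a].size(), nB = R[b].size();
      const int va = nvalid[a], vb = nvalid[b];
      kmat.assign((size_t)va * vb, 0);

      // identity counts for every (j, q) via running sums along diagonals
      for (int d = -(nB - 1); d <= nA - 1; ++d) {
        int i0 = std::max(0, d), i1 = std::min(nA - 1, nB - 1 + d);
        if (i1 - i0 + 1 < l) continue;
        int sum = 0;
        for (int i = i0; i <= i1; ++i) {
          int ai = R[a][i], bi = R[b][i - d];
          int match = (ai == bi && ai < 4) ? 1 : 0;
          sum += match;
          if (i - i0 >= l) {
            int aj = R[a][i - l], bj = R[b][i - l - d];
            sum -= (aj == bj && aj < 4) ? 1 : 0;
          }
          if (i - i0 >= l - 1) {
            int j = i - l + 1, q = i - d - l + 1;
            if (j < va && q < vb)
              kmat[(size_t)j * vb + q] = (signed char)sum;
          }
        }
      }

      // weighted scores and the rank threshold over this row pair
      fpmat.assign((size_t)va * vb, 0.0);
      pos_fp.clear();
      for (int j = 0; j < va; ++j) {
        const double wa = W[a][j];
        for (int q = 0; q < vb; ++q) {
          int k = kmat[(size_t)j * vb + q];
          if (k == 0) continue;
          double fp = fk[k] * (wa + W[b][q]);
          if (fp > 0.0) {
            fpmat[(size_t)j * vb + q] = fp;
            pos_fp.push_back(fp);
          }
        }
      }
      double rank_cut = R_PosInf;
      if ((int)pos_fp.size() > 0) {
        if ((int)pos_fp.size() <= topk) {
          rank_cut = *std::min_element(pos_fp.begin(), pos_fp.end());
        } else {
          std::nth_element(pos_fp.begin(), pos_fp.begin() + (topk - 1),
                           pos_fp.end(), std::greater<double>());
          rank_cut = pos_fp[topk - 1];
        }
      }

      for (int j = 0; j < va; ++j) {
        for (int q = 0; q < vb; ++q) {
          int k = kmat[(size_t)j * vb + q];
          if (k == 0) continue;
          double fp = fpmat[(size_t)j * vb + q];
          bool by_rank = fp > 0.0 && fp >= rank_cut;
          if (emit_edges) {
            if (by_rank) {
              e_row_a.push_back(a + 1);
              e_pos_a.push_back(j + 1);
              e_row_b.push_back(b + 1);
              e_pos_b.push_back(q + 1);
              e_w.push_back(fp);
            }
          } else if (k >= kmin || by_rank) {
            ++C[a][j];
            ++C[b][q];
          }
        }
      }
    }
  }

  if (emit_edges) {
    return List::create(
      _["row_a"] = wrap(e_row_a), _["pos_a"] = wrap(e_pos_a),
      _["row_b"] = wrap(e_row_b), _["pos_b"] = wrap(e_pos_b),
      _["weight"] = wrap(e_w));
  }
  return counts;
}

// Sliding-window maximum of x over [i - hw, i + hw], truncated at the ends;
// used to aggregate first-pass support over the +/- 2 bp neighborhood.

// [[Rcpp::export]]
NumericVector cpp_window_max(NumericVector x, int hw) {
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double m = R_NegInf;
    int j0 = std::max(0, i - hw), j1 = std::min(n - 1, i + hw);
    for (int j = j0; j <= j1; ++j) m = std::max(m, x[j]);
    out[i] = m;
  }
  return out;
}

// Match scores of every width-lx segment of one row: the coverage window
// factor times the PWM log-odds sum; N bases take the column mean.

// [[Rcpp::export]]
NumericVector cpp_score_segments(IntegerVector row, NumericMatrix pwm,
                                 NumericVector w, int t, int lo) {
  const int n = row.size(), lx = pwm.ncol();
  const int nv = n - lx + 1;
  if (nv < 1) return NumericVector(0);
  NumericVector colmean(lx);
  for (int j = 0; j < lx; ++j) {
    double s = 0;
    for (int i = 0; i < 4; ++i) s += pwm(i, j);
    colmean[j] = s / 4.0;
  }
  NumericVector out(nv);
  for (int start = 0; start < nv; ++start) {
    double s = 0;
    for (int j = 0; j < lx; ++j) {
      int b = row[start + j];
      s += (b < 4) ? pwm(b, j) : colmean[j];
    }
    double w1 = R_NegInf, w2 = R_NegInf;
    for (int j = std::max(0, start - t); j <= start; ++j)
      w1 = std::max(w1, w[j]);
    for (int j = start; j <= std::min(n - 1, start + lo + t); ++j)
      w2 = std::max(w2, w[j]);
    out[start] = 0.5 * (w1 + w2) * s;
  }
  return out;
}
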