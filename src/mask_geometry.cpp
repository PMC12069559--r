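#include <Rcpp.h>
using namespace Rcpp;

// Per-frame pixel pass over a uint8 label stack (H x W x T, column-major):
// glottal-area pixel count, adjacency-based landmark candidates and bounding
// boxes. Labels: 0 background, 1 glottis, 2 right fold, 3 left fold.
//
// Landmark rules (see detect_endpoints() for the reference R implementation):
//   P_r / P_l : most dorsal (min row) pixel of the respective fold that is
//               8-adjacent to the other fold or the glottis; ties -> mean col.
//   A         : most ventral (max row) pixel of the fold-fold adjacency set;
//               if the folds never touch, most ventral fold pixel adjacent to
//               the glottis. Ties -> mean col.
//   Full closure (no glottis pixels): P_r and P_l collapse to their midpoint.
// [[Rcpp::export]]
List mask_stats_cpp(RawVector frames, int H, int W, int T) {
  IntegerVector gaw(T);
  NumericMatrix lm(T, 6); // pr_row, pr_col, pl_row, pl_col, a_row, a_col
  IntegerMatrix bbox(T, 4); // rmin, rmax, cmin, cmax (1-based)
  LogicalVector ok(T);
  const Rbyte* p = RAW(frames);
  const long frame_sz = (long)H * W;

  for (int t = 0; t < T; ++t) {
    const Rbyte* f = p + (long)t * frame_sz;
    int n_glottis = 0;
    int rmin = H, rmax = -1, cmin = W, cmax = -1;
    // extremes trackers: row, col-sum, count
    int prow[2] = {H, H};          // dorsal boundary per side (0 = right, 1 = left)
    double pcol[2] = {0, 0}; int pcnt[2] = {0, 0};
    int arow_contact = -1; double acol_contact = 0; int acnt_contact = 0;
    int arow_any = -1; double acol_any = 0; int acnt_any = 0;

    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        int v = f[r + (long)c * H];
        if (v == 0 || v > 3) continue;
        if (r < rmin) rmin = r;
        if (r > rmax) rmax = r;
        if (c < cmin) cmin = c;
        if (c > cmax) cmax = c;
        if (v == 1) { ++n_glottis; continue; }
        int other = (v == 2) ? 3 : 2;
        bool adj_other = false, adj_glottis = false;
        for (int dc = -1; dc <= 1; ++dc) {
          int cc = c + dc;
          if (cc < 0 || cc >= W) continue;
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int rr = r + dr;
            if (rr < 0 || rr >= H) continue;
            int nv = f[rr + (long)cc * H];
            if (nv == other) adj_other = true;
            else if (nv == 1) adj_glottis = true;
          }
        }
        if (!(adj_other || adj_glottis)) continue;
        int s = (v == 2) ? 0 : 1;
        if (r < prow[s]) { prow[s] = r; pcol[s] = c; pcnt[s] = 1; }
        else if (r == prow[s]) { pcol[s] += c; ++pcnt[s]; }
        if (adj_other) {
          if (r > arow_contact) { arow_contact = r; acol_contact = c; acnt_contact = 1; }
          else if (r == arow_contact) { acol_contact += c; ++acnt_contact; }
        }
        if (r > arow_any) { arow_any = r; acol_any = c; acnt_any = 1; }
        else if (r == arow_any) { acol_any += c; ++acnt_any; }
      }
    }

    gaw[t] = n_glottis;
    bbox(t, 0) = rmin + 1; bbox(t, 1) = rmax + 1;
    bbox(t, 2) = cmin + 1; bbox(t, 3) = cmax + 1;
    bool good = (pcnt[0] > 0) && (pcnt[1] > 0) &&
                (arow_contact >= 0 || arow_any >= 0);
    ok[t] = good;
    if (!good) {
      for (int k = 0; k < 6; ++k) lm(t, k) = NA_REAL;
      continue;
    }
    double pr_r = prow[0] + 1.0, pr_c = pcol[0] / pcnt[0] + 1.0;
    double pl_r = prow[1] + 1.0, pl_c = pcol[1] / pcnt[1] + 1.0;
    if (n_glottis == 0) { // complete closure: shared posterior point
      double mr = 0.5 * (pr_r + pl_r), mc = 0.5 * (pr_c + pl_c);
      pr_r = pl_r = mr; pr_c = pl_c = mc;
    }
    lm(t, 0) = pr_r; lm(t, 1) = pr_c;
    lm(t, 2) = pl_r; lm(t, 3) = pl_c;
    if (arow_contact >= 0) {
      lm(t, 4) = arow_contact + 1.0;
      lm(t, 5) = acol_contact / acnt_contact + 1.0;
    } else {
      lm(t, 4) = arow_any + 1.0;
      lm(t, 5) = acol_any / acnt_any + 1.0;
    }
  }
  return List::create(_["gaw"] = gaw, _["landmarks"] = lm,
                      _["bbox"] = bbox, _["ok"] = ok);
}
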