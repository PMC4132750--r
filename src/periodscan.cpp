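#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// base codes: A=0 C=1 G=2 T=3 N=4

static inline int rand_index(int n) {
  // uniform on 0..n-1 from R's RNG
  int j = (int)(unif_rand() * n);
  if (j >= n) j = n - 1;
  return j;
}

// Dinucleotide-preserving (k=2) Euler-path shuffle, Altschul-Erickson
// construction as used by uShuffle: random last-edge arborescence toward the
// terminal vertex, random ordering of the remaining edges, then an Euler walk
// from the first character. Preserves the exact dinucleotide count vector and
// the first and last characters. Alphabet is the 5 codes (N is an ordinary
// letter, so runs of N are preserved too).
static std::vector<int> dinuc_shuffle_codes(const std::vector<int>& s) {
  const int L = (int)s.size();
  if (L <= 3) return s;
  std::vector<std::vector<int>> adj(5);
  for (int i = 0; i < L - 1; ++i) adj[s[i]].push_back(s[i + 1]);
  const int last = s[L - 1];

  // vertices with outgoing edges, excluding the end vertex
  std::vector<int> verts;
  for (int v = 0; v < 5; ++v)
    if (v != last && !adj[v].empty()) verts.push_back(v);

  // rejection-sample a random arborescence of "last edges" toward `last`
  int lastTarget[5] = {-1, -1, -1, -1, -1};
  for (int attempt = 0; ; ++attempt) {
    for (int v : verts) lastTarget[v] = adj[v][rand_index((int)adj[v].size())];
    bool ok = true;
    for (int v : verts) {
      int cur = v, steps = 0;
      while (cur != last) {
        if (adj[cur].empty() || lastTarget[cur] < 0 || ++steps > 6) { ok = false; break; }
        cur = lastTarget[cur];
      }
      if (!ok) break;
    }
    if (ok) break;
    if (attempt > 100000) stop("dinucleotide shuffle: arborescence sampling failed");
  }

  // order edge lists: random permutation, chosen last edge moved to the end
  for (int v = 0; v < 5; ++v) {
    std::vector<int>& e = adj[v];
    if (e.empty()) continue;
    if (v != last && lastTarget[v] >= 0) {
      // remove one instance of the chosen last edge
      for (size_t i = 0; i < e.size(); ++i)
        if (e[i] == lastTarget[v]) { e[i] = e.back(); e.pop_back(); break; }
    }
    for (int i = (int)e.size() - 1; i > 0; --i)
      std::swap(e[i], e[rand_index(i + 1)]);
    if (v != last && lastTarget[v] >= 0) e.push_back(lastTarget[v]);
  }

  // Euler walk
  std::vector<int> out(L);
  int ptr[5] = {0, 0, 0, 0, 0};
  int cur = s[0];
  out[0] = cur;
  for (int i = 1; i < L; ++i) {
    cur = adj[cur][ptr[cur]++];
    out[i] = cur;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector dinuc_shuffle_cpp(IntegerVector seq) {
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<int> out = dinuc_shuffle_codes(s);
  return IntegerVector(out.begin(), out.end());
}

// raw pair-count autocorrelation: (1/(M-k)) sum_i x_i x_{i+k}, k = 1..k_hi
// [[Rcpp::export]]
NumericVector acf_raw_cpp(NumericVector x, int k_hi) {
  const int M = x.size();
  if (M <= k_hi) stop("track shorter than k_hi");
  NumericVector out(k_hi);
  for (int k = 1; k <= k_hi; ++k) {
    double s = 0.0;
    for (int i = 0; i + k < M; ++i) s += x[i] * x[i + k];
    out[k - 1] = s / (double)(M - k);
  }
  return out;
}

static void smooth_trunc(const std::vector<double>& x, int width,
                         std::vector<double>& out) {
  const int n = (int)x.size();
  const int h = (width - 1) / 2;
  for (int i = 0; i < n; ++i) {
    int lo = i - h < 0 ? 0 : i - h;
    int hi = i + h >= n ? n - 1 : i + h;
    double s = 0.0;
    for (int j = lo; j <= hi; ++j) s += x[j];
    out[i] = s / (double)(hi - lo + 1);
  }
}

// Null ensemble for a genomic window: n_perm dinucleotide shuffles, each run
// through indicator track -> ACF -> smoothing -> mean-subtracted power on the
// period grid encoded by cosA/sinA ((k_max-k_min+1) x n_grid), then normalized
// to unit grid mean (degenerate rows all zero). Mirrors the R spectrum path
// exactly; cross-checked in tests.
// [[Rcpp::export]]
NumericMatrix null_spectra_cpp(IntegerVector seq, LogicalMatrix motif,
                               int n_perm, int k_min, int k_max,
                               int smooth_w, NumericMatrix cosA,
                               NumericMatrix sinA) {
  const int L = seq.size();
  const int M = L - 1;
  const int nk = k_max - k_min + 1;
  const int ng = cosA.ncol();
  if (cosA.nrow() != nk || sinA.nrow() != nk || sinA.ncol() != ng)
    stop("angle table dimensions do not match the lag window");
  if (M <= k_max) stop("window shorter than k_max + 1");
  std::vector<int> s(seq.begin(), seq.end());
  bool mot[5][5];
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b) mot[a][b] = motif(a, b);

  NumericMatrix out(n_perm, ng);
  std::vector<double> x(M), acf(k_max), sm(k_max), P(ng);
  for (int r = 0; r < n_perm; ++r) {
    std::vector<int> sh = dinuc_shuffle_codes(s);
    double n1 = 0.0;
    for (int i = 0; i < M; ++i) {
      x[i] = mot[sh[i]][sh[i + 1]] ? 1.0 : 0.0;
      n1 += x[i];
    }
    if (n1 == 0.0) continue;                 // degenerate: row stays zero
    const double p2 = (n1 / M) * (n1 / M);
    for (int k = 1; k <= k_max; ++k) {
      double sum = 0.0;
      for (int i = 0; i + k < M; ++i) sum += x[i] * x[i + k];
      acf[k - 1] = sum / ((double)(M - k) * p2);
    }
    smooth_trunc(acf, smooth_w, sm);
    double m = 0.0;
    for (int k = k_min; k <= k_max; ++k) m += sm[k - 1];
    m /= (double)nk;
    double tot = 0.0;
    for (int g = 0; g < ng; ++g) {
      double re = 0.0, im = 0.0;
      for (int j = 0; j < nk; ++j) {
        const double y = sm[k_min - 1 + j] - m;
        re += y * cosA(j, g);
        im += y * sinA(j, g);
      }
      P[g] = (re * re + im * im) / (double)nk;
      tot += P[g];
    }
    if (tot < 1e-12) continue;
    for (int g = 0; g < ng; ++g) out(r, g) = P[g] * ng / tot;
  }
  return out;
}
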