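#include <Rcpp.h>
using namespace Rcpp;

// Pairwise alignment under the package-wide scoring convention:
//   match +1, mismatch -1, gap -1 per gapped column (linear),
//   tie-break diagonal > up (gap in b) > left (gap in a).
// The tie-break is part of the contract: it makes the match count of the
// optimal alignment unambiguous, so pure-R oracle re-implementations in the
// test suite can reproduce it exactly.

struct Cell {
  int score;
  int matches;
  int columns;
};

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
    case 'A': r[i] = 'T'; break;
    case 'C': r[i] = 'G'; break;
    case 'G': r[i] = 'C'; break;
    case 'T': r[i] = 'A'; break;
    case 'a': r[i] = 't'; break;
    case 'c': r[i] = 'g'; break;
    case 'g': r[i] = 'c'; break;
    case 't': r[i] = 'a'; break;
    default: break; // N etc. left as-is
    }
  }
  return r;
}

struct Workspace {
  std::vector<int> prevS, prevM, prevC, curS, curM, curC;
  void ensure(int n2) {
    if ((int) prevS.size() < n2 + 1) {
      prevS.resize(n2 + 1); prevM.resize(n2 + 1); prevC.resize(n2 + 1);
      curS.resize(n2 + 1); curM.resize(n2 + 1); curC.resize(n2 + 1);
    }
  }
};

static Cell align_pair_ws(const std::string& a, const std::string& b,
                          bool local, Workspace& ws) {
  const int n1 = (int) a.size(), n2 = (int) b.size();
  ws.ensure(n2);
  std::vector<int>& prevS = ws.prevS; std::vector<int>& prevM = ws.prevM;
  std::vector<int>& prevC = ws.prevC; std::vector<int>& curS = ws.curS;
  std::vector<int>& curM = ws.curM;  std::vector<int>& curC = ws.curC;

  for (int j = 0; j <= n2; ++j) {
    prevS[j] = local ? 0 : -j;
    prevM[j] = 0;
    prevC[j] = local ? 0 : j;
  }
  Cell best = {0, 0, 0}; // local best; for global, overwritten by the corner
  for (int i = 1; i <= n1; ++i) {
    curS[0] = local ? 0 : -i;
    curM[0] = 0;
    curC[0] = local ? 0 : i;
    const char ai = a[i - 1];
    for (int j = 1; j <= n2; ++j) {
      const bool eq = (ai == b[j - 1]);
      const int sd = prevS[j - 1] + (eq ? 1 : -1);
      const int su = prevS[j] - 1;
      const int sl = curS[j - 1] - 1;
      int s, m, c;
      if (sd >= su && sd >= sl) {
        s = sd; m = prevM[j - 1] + (eq ? 1 : 0); c = prevC[j - 1] + 1;
      } else if (su >= sl) {
        s = su; m = prevM[j]; c = prevC[j] + 1;
      } else {
        s = sl; m = curM[j - 1]; c = curC[j - 1] + 1;
      }
      if (local && s <= 0) { s = 0; m = 0; c = 0; }
      curS[j] = s; curM[j] = m; curC[j] = c;
      if (local && s > best.score) best = {s, m, c};
    }
    std::swap(prevS, curS); std::swap(prevM, curM); std::swap(prevC, curC);
  }
  if (!local) best = {prevS[n2], prevM[n2], prevC[n2]};
  return best;
}

static Cell align_pair(const std::string& a, const std::string& b, bool local) {
  Workspace ws;
  return align_pair_ws(a, b, local, ws);
}

//' @noRd
// [[Rcpp::export(name = ".align_stats_cpp")]]
IntegerVector align_stats_cpp(std::string a, std::string b, bool local) {
  Cell r = align_pair(a, b, local);
  return IntegerVector::create(_["score"] = r.score, _["matches"] = r.matches,
                               _["columns"] = r.columns);
}

// Best probe-match identity per fragment: local-align each candidate
// (probe, strand) pair and report max matches/max(columns, min_len).
// cand_probe[i]: 1-based probe indices; cand_strand[i]: 0 = forward probe,
// 1 = reverse-complemented probe. max_span > 0 truncates the fragment to its
// first max_span bases (used for background-identity estimates only).
// [[Rcpp::export(name = ".best_probe_identity_cpp")]]
NumericVector best_probe_identity_cpp(CharacterVector fragments,
                                      CharacterVector probes,
                                      List cand_probe, List cand_strand,
                                      int min_len,
                                      IntegerVector max_span) {
  const int nf = fragments.size(), np = probes.size();
  std::vector<std::string> fwd(np), rev(np);
  for (int p = 0; p < np; ++p) {
    fwd[p] = as<std::string>(probes[p]);
    rev[p] = revcomp_str(fwd[p]);
  }
  NumericVector out(nf);
  Workspace ws;
  for (int i = 0; i < nf; ++i) {
    std::string frag = as<std::string>(fragments[i]);
    const int span = max_span[i];
    if (span > 0 && (int) frag.size() > span) frag = frag.substr(0, span);
    IntegerVector cand = cand_probe[i];
    IntegerVector strands = cand_strand[i];
    if (cand.size() != strands.size()) stop("candidate list length mismatch");
    double x = 0.0;
    for (int k = 0; k < cand.size(); ++k) {
      const int p = cand[k] - 1;
      if (p < 0 || p >= np) stop("candidate probe index out of range");
      Cell r = align_pair_ws(frag, strands[k] == 0 ? fwd[p] : rev[p], true, ws);
      const int denom = std::max(r.columns, min_len);
      if (denom > 0) {
        const double id = (double) r.matches / (double) denom;
        if (id > x) x = id;
      }
    }
    out[i] = x;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Local (Smith-Waterman) affine-gap alignment of sequences against a
// position-specific scoring matrix; returns the best local score per sequence.
// prof: L x A matrix of per-column symbol scores, alphabet maps columns of prof.
// [[Rcpp::export(name = ".pssm_best_scores_cpp")]]
NumericVector pssm_best_scores_cpp(NumericMatrix prof, CharacterVector seqs,
                                   std::string alphabet,
                                   double gap_open, double gap_extend) {
  const int L = prof.nrow(), A = prof.ncol();
  if ((int) alphabet.size() != A) stop("alphabet length must equal ncol(prof)");
  int code[256];
  std::fill(code, code + 256, -1);
  for (int k = 0; k < A; ++k) {
    code[(unsigned char) alphabet[k]] = k;
    code[(unsigned char) std::tolower(alphabet[k])] = k;
  }
  const double NEG = -1e9;
  const int ns = seqs.size();
  NumericVector out(ns);
  for (int s = 0; s < ns; ++s) {
    std::string q = as<std::string>(seqs[s]);
    const int n = (int) q.size();
    // rows: profile columns (i), cols: sequence (j); rolling rows
    std::vector<double> Hp(n + 1, 0.0), Fp(n + 1, NEG);
    std::vector<double> Hc(n + 1), Fc(n + 1);
    double best = 0.0;
    for (int i = 1; i <= L; ++i) {
      Hc[0] = 0.0; Fc[0] = NEG;
      double E = NEG; // gap in the profile (consume sequence)
      for (int j = 1; j <= n; ++j) {
        const int cj = code[(unsigned char) q[j - 1]];
        const double sub = (cj >= 0) ? prof(i - 1, cj) : -4.0;
        E = std::max(Hc[j - 1] - gap_open, E - gap_extend);
        Fc[j] = std::max(Hp[j] - gap_open, Fp[j] - gap_extend);
        double h = Hp[j - 1] + sub;
        if (E > h) h = E;
        if (Fc[j] > h) h = Fc[j];
        if (h < 0.0) h = 0.0;
        Hc[j] = h;
        if (h > best) best = h;
      }
      std::swap(Hp, Hc); std::swap(Fp, Fc);
    }
    out[s] = best;
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = revcomp_str(as<std::string>(x[i]));
  out.names() = x.names();
  return out;
}
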