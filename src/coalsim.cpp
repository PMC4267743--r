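#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Back-in-time coalescent with crossover and gene conversion; mirrors the
// documented event rates (coalescence k(k-1)/2, per-lineage crossover
// rho*L/2, per-lineage conversion gamma*L/2 with exponential tract length).
// Uses R's RNG stream so results are reproducible under set.seed().

namespace {

struct Seg { double l, r; int node; };  // node ids are 1-based
typedef std::vector<Seg> Lin;

struct NodeStore {
  std::vector<double> time;
  std::vector<int> c1, c2, nl;
  int add(double t, int a, int b) {
    time.push_back(t); c1.push_back(a); c2.push_back(b);
    nl.push_back(nl[a - 1] + nl[b - 1]);
    return (int)time.size();
  }
};

struct DoneIv { double l, r; int root; };

// node covering position x, or 0
int node_at(const Lin &s, double x) {
  for (size_t i = 0; i < s.size(); ++i)
    if (s[i].l <= x && x < s[i].r) return s[i].node;
  return 0;
}

Lin clip(const Lin &s, double lo, double hi) {
  Lin out;
  for (size_t i = 0; i < s.size(); ++i) {
    double l = std::max(s[i].l, lo), r = std::min(s[i].r, hi);
    if (l < r) out.push_back({l, r, s[i].node});
  }
  return out;
}

Lin outside(const Lin &s, double lo, double hi) {
  Lin out = clip(s, -1e300, lo), right = clip(s, hi, 1e300);
  out.insert(out.end(), right.begin(), right.end());
  return out;
}

Lin merge_lin(const Lin &a, const Lin &b, double t, int n, NodeStore &nd,
              std::vector<DoneIv> &done) {
  std::vector<double> bp;
  for (size_t i = 0; i < a.size(); ++i) { bp.push_back(a[i].l); bp.push_back(a[i].r); }
  for (size_t i = 0; i < b.size(); ++i) { bp.push_back(b[i].l); bp.push_back(b[i].r); }
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());
  Lin out;
  // runs of elementary intervals sharing the same (node_a, node_b) pair
  double run_l = 0, run_r = 0; int run_a = 0, run_b = 0; bool open = false;
  auto flush = [&]() {
    if (!open) return;
    if (run_a > 0 && run_b > 0) {
      int v = nd.add(t, run_a, run_b);
      if (nd.nl[v - 1] == n) done.push_back({run_l, run_r, v});
      else out.push_back({run_l, run_r, v});
    } else out.push_back({run_l, run_r, std::max(run_a, run_b)});
    open = false;
  };
  for (size_t i = 0; i + 1 < bp.size(); ++i) {
    double lo = bp[i], hi = bp[i + 1], mid = 0.5 * (lo + hi);
    int na = node_at(a, mid), nb = node_at(b, mid);
    if (na == 0 && nb == 0) { flush(); continue; }
    if (open && na == run_a && nb == run_b && lo == run_r) {
      run_r = hi;
      continue;
    }
    flush();
    run_l = lo; run_r = hi; run_a = na; run_b = nb; open = true;
  }
  flush();
  return out;
}

} // namespace

// [[Rcpp::export(name = ".coalsim_cpp")]]
List coalsim_cpp(int n, double L, double rho, double gamma, double lam,
                 double theta, double max_events) {
  if (n < 2 || L <= 0) stop("need n >= 2 and L > 0");
  if (gamma > 0 && lam <= 0) stop("lam must be > 0 when gamma > 0");
  RNGScope scope;
  NodeStore nd;
  nd.time.assign(n, 0.0); nd.c1.assign(n, 0); nd.c2.assign(n, 0);
  nd.nl.assign(n, 1);
  std::vector<DoneIv> done;
  std::vector<Lin> lin(n);
  for (int i = 0; i < n; ++i) lin[i].push_back({0.0, L, i + 1});
  double t = 0; double events = 0;
  std::vector<double> tracts;
  while (lin.size() >= 2) {
    double k = (double)lin.size();
    double rc = k * (k - 1) / 2, rr = k * rho * L / 2, rg = k * gamma * L / 2;
    double total = rc + rr + rg;
    t += exp_rand() / total;
    if (++events > max_events)
      stop("event cap exceeded; reduce rho/gamma or the region length");
    double u = unif_rand() * total;
    if (u < rc) {
      int i = (int)(unif_rand() * k); if (i >= (int)k) i = (int)k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j >= (int)k - 1) j = (int)k - 2;
      if (j >= i) ++j;
      Lin merged = merge_lin(lin[i], lin[j], t, n, nd, done);
      if (i < j) std::swap(i, j);      // erase the larger index first
      lin.erase(lin.begin() + i);
      lin.erase(lin.begin() + j);
      if (!merged.empty()) lin.push_back(merged);
    } else if (u < rc + rr) {
      int i = (int)(unif_rand() * k); if (i >= (int)k) i = (int)k - 1;
      double b = unif_rand() * L;
      Lin left = clip(lin[i], -1e300, b), right = clip(lin[i], b, 1e300);
      if (!left.empty() && !right.empty()) {
        lin[i] = left;
        lin.push_back(right);
      }
    } else {
      int i = (int)(unif_rand() * k); if (i >= (int)k) i = (int)k - 1;
      double s = unif_rand() * L;
      double len = exp_rand() * lam;
      tracts.push_back(len);
      Lin ins = clip(lin[i], s, s + len), outs = outside(lin[i], s, s + len);
      if (!ins.empty() && !outs.empty()) {
        lin[i] = ins;
        lin.push_back(outs);
      }
    }
  }
  std::sort(done.begin(), done.end(),
            [](const DoneIv &a, const DoneIv &b) { return a.l < b.l; });

  // infinite-sites mutations on each interval's marginal tree
  std::vector<double> pos;
  std::vector<std::vector<int>> carriers;
  std::vector<int> sub_nodes; std::vector<double> sub_br;
  for (size_t iv = 0; iv < done.size() && theta > 0; ++iv) {
    sub_nodes.clear(); sub_br.clear();
    std::vector<std::pair<int, double>> stack;  // (node, parent time)
    stack.push_back({nd.c1[done[iv].root - 1], nd.time[done[iv].root - 1]});
    stack.push_back({nd.c2[done[iv].root - 1], nd.time[done[iv].root - 1]});
    double tlen = 0;
    while (!stack.empty()) {
      int v = stack.back().first; double pt = stack.back().second;
      stack.pop_back();
      sub_nodes.push_back(v);
      double br = pt - nd.time[v - 1];
      sub_br.push_back(br); tlen += br;
      if (nd.c1[v - 1] > 0) {
        stack.push_back({nd.c1[v - 1], nd.time[v - 1]});
        stack.push_back({nd.c2[v - 1], nd.time[v - 1]});
      }
    }
    double width = done[iv].r - done[iv].l;
    int nmut = (int)R::rpois(theta / 2 * width * tlen);
    for (int m = 0; m < nmut; ++m) {
      double u = unif_rand() * tlen, acc = 0;
      size_t pick = sub_nodes.size() - 1;
      for (size_t q = 0; q < sub_br.size(); ++q) {
        acc += sub_br[q];
        if (u <= acc) { pick = q; break; }
      }
      pos.push_back(done[iv].l + unif_rand() * width);
      std::vector<int> leaves;
      std::vector<int> st2(1, sub_nodes[pick]);
      while (!st2.empty()) {
        int v = st2.back(); st2.pop_back();
        if (nd.c1[v - 1] == 0) leaves.push_back(v);
        else { st2.push_back(nd.c1[v - 1]); st2.push_back(nd.c2[v - 1]); }
      }
      carriers.push_back(leaves);
    }
  }
  int S = (int)pos.size();
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return pos[a] < pos[b]; });
  IntegerMatrix alle(n, S);
  NumericVector poss(S);
  for (int j = 0; j < S; ++j) {
    poss[j] = pos[ord[j]];
    const std::vector<int> &cv = carriers[ord[j]];
    for (size_t q = 0; q < cv.size(); ++q) alle(cv[q] - 1, j) = 1;
  }
  NumericMatrix ivm((int)done.size(), 3);
  for (size_t i = 0; i < done.size(); ++i) {
    ivm(i, 0) = done[i].l; ivm(i, 1) = done[i].r; ivm(i, 2) = done[i].root;
  }
  colnames(ivm) = CharacterVector::create("left", "right", "root");
  return List::create(
    _["alleles"] = alle, _["positions"] = poss, _["intervals"] = ivm,
    _["time"] = wrap(nd.time), _["c1"] = wrap(nd.c1), _["c2"] = wrap(nd.c2),
    _["nleaves"] = wrap(nd.nl), _["tracts"] = wrap(tracts),
    _["n_events"] = events);
}
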