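#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Semi-global ("fitting") alignment of short amplicon reads against a
// reference: the read is aligned end-to-end, reference end gaps are free.
// Affine gap penalty: a gap of length L costs gap_open + L * gap_ext.
// Candidate diagonals are located by exact k-mer seeding so the DP can be
// banded; reads without seeds fall back to the full matrix.

static const int NEG = INT_MIN / 4;
static const int SEED_K = 12;
static const int SEED_STRIDE = 4;
static const int BAND_MARGIN = 40;     // extra diagonals beyond seeded range
static const int DIAG_CLUSTER = 80;    // seeds further than this from the modal
                                       // diagonal are treated as spurious

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

typedef std::unordered_map<uint32_t, std::vector<int> > KmerIndex;

static KmerIndex index_kmers(const std::string& s) {
  KmerIndex idx;
  const int n = (int) s.size();
  uint32_t key = 0, mask = (1u << (2 * SEED_K)) - 1u;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t) c) & mask;
    if (++valid >= SEED_K) idx[key].push_back(i - SEED_K + 1);
  }
  return idx;
}

// Seeded diagonals (ref_pos - read_pos) for one read; empty if no seed hits.
static std::vector<int> seed_diagonals(const std::string& read, const KmerIndex& idx) {
  std::vector<int> diags;
  const int m = (int) read.size();
  for (int p = 0; p + SEED_K <= m; p += SEED_STRIDE) {
    uint32_t key = 0;
    bool ok = true;
    for (int t = 0; t < SEED_K; ++t) {
      int c = base_code(read[p + t]);
      if (c < 0) { ok = false; break; }
      key = (key << 2) | (uint32_t) c;
    }
    if (!ok) continue;
    KmerIndex::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    for (size_t u = 0; u < it->second.size(); ++u)
      diags.push_back(it->second[u] - p);
  }
  return diags;
}

// Modal-diagonal clustering -> band [lo, hi] over d = j - i (0-based).
static bool seed_band(const std::vector<int>& diags, int& lo, int& hi) {
  if (diags.empty()) return false;
  std::unordered_map<int, int> votes;
  for (size_t u = 0; u < diags.size(); ++u) ++votes[diags[u]];
  int best_d = diags[0], best_v = 0;
  for (std::unordered_map<int, int>::iterator it = votes.begin(); it != votes.end(); ++it)
    if (it->second > best_v || (it->second == best_v && it->first < best_d)) {
      best_v = it->second; best_d = it->first;
    }
  int dmin = best_d, dmax = best_d;
  for (size_t u = 0; u < diags.size(); ++u) {
    int d = diags[u];
    if (std::abs(d - best_d) <= DIAG_CLUSTER) {
      dmin = std::min(dmin, d);
      dmax = std::max(dmax, d);
    }
  }
  lo = dmin - BAND_MARGIN;
  hi = dmax + BAND_MARGIN;
  return true;
}

struct OpRun {              // one run of alignment columns
  int type;                 // 0 '=', 1 'X', 2 'D' (ref gapped out), 3 'I'
  int ref_start;            // 0-based; for 'I' the anchor (ref pos following)
  int len;
  int read_start;           // 0-based offset in the oriented read; for 'D'
                            // the read offset following the deletion
};

struct AlnResult {
  bool ok;
  int score, ref_start, ref_end;   // half-open 0-based reference span
  std::vector<OpRun> ops;
};

class Aligner {
public:
  Aligner(const std::string& ref, int match, int mismatch, int gap_open, int gap_ext)
      : ref_(ref), n_((int) ref.size()), match_(match), mismatch_(mismatch),
        open_(gap_open), ext_(gap_ext), cap_(0) {}

  // band over diagonals d = j - i; pass lo <= -m, hi >= n for full DP
  AlnResult align(const std::string& read, int lo_d, int hi_d) {
    const int m = (int) read.size();
    ensure(m);
    AlnResult res; res.ok = false; res.score = NEG;
    const int W = n_ + 1;

    // row 0: alignment may start before any reference position
    for (int j = 0; j <= n_; ++j) {
      M_[j] = 0; D_[j] = NEG; I_[j] = NEG;
    }
    for (int i = 1; i <= m; ++i) {
      const int row = i * W;
      const int prow = row - W;
      int jlo = std::max(0, i + lo_d);
      int jhi = std::min(n_, i + hi_d);
      if (jlo > jhi) return res;
      int pjlo = std::max(0, (i - 1) + lo_d);   // previous row's band
      int pjhi = std::min(n_, (i - 1) + hi_d);
      const int ci = base_code(read[i - 1]);
      for (int j = jlo; j <= jhi; ++j) {
        int mv = NEG, dv = NEG, iv = NEG;
        uint8_t mt = 0, dt = 0, it = 0;
        if (j >= 1 && j - 1 >= pjlo && j - 1 <= pjhi) {
          // match/mismatch from (i-1, j-1)
          int s = (ci >= 0 && ci == base_code(ref_[j - 1])) ? match_ : mismatch_;
          int a = M_[prow + j - 1], b = D_[prow + j - 1], c = I_[prow + j - 1];
          mv = a; mt = 0;
          if (b > mv) { mv = b; mt = 1; }
          if (c > mv) { mv = c; mt = 2; }
          mv = (mv <= NEG) ? NEG : mv + s;
        }
        if (j >= 1 && j - 1 >= jlo) {
          // gap in read: reference base j skipped, from (i, j-1)
          int a = M_[row + j - 1] - (open_ + ext_);
          int b = D_[row + j - 1] - ext_;
          int c = I_[row + j - 1] - (open_ + ext_);
          dv = a; dt = 0;
          if (b > dv) { dv = b; dt = 1; }
          if (c > dv) { dv = c; dt = 2; }
          if (dv < NEG / 2) dv = NEG;
        }
        if (j >= pjlo && j <= pjhi) {
          // gap in reference: read base i inserted, from (i-1, j)
          int a = M_[prow + j] - (open_ + ext_);
          int b = I_[prow + j] - ext_;
          int c = D_[prow + j] - (open_ + ext_);
          iv = a; it = 0;
          if (b > iv) { iv = b; it = 2; }
          if (c > iv) { iv = c; it = 1; }
          if (iv < NEG / 2) iv = NEG;
        }
        M_[row + j] = mv; D_[row + j] = dv; I_[row + j] = iv;
        TB_[row + j] = (uint8_t) (mt | (dt << 2) | (it << 4));
      }
      // cells just outside the band must not leak stale values
      if (jlo > 0 && jlo - 1 >= 0) { M_[row + jlo - 1] = D_[row + jlo - 1] = I_[row + jlo - 1] = NEG; }
      if (jhi < n_) { M_[row + jhi + 1] = D_[row + jhi + 1] = I_[row + jhi + 1] = NEG; }
    }

    // best end: all of the read consumed, free reference suffix
    int best = NEG, bj = -1, bstate = 0;
    const int row = m * W;
    int jlo = std::max(0, m + lo_d), jhi = std::min(n_, m + hi_d);
    for (int j = jlo; j <= jhi; ++j) {
      if (M_[row + j] > best) { best = M_[row + j]; bj = j; bstate = 0; }
      if (I_[row + j] > best) { best = I_[row + j]; bj = j; bstate = 2; }
    }
    if (bj < 0 || best <= NEG / 2) return res;

    // traceback
    std::vector<OpRun> rev;
    int i = m, j = bj, state = bstate;
    while (i > 0) {
      uint8_t tb = TB_[i * W + j];
      if (state == 0) {          // column: read[i-1] vs ref[j-1]
        int ci = base_code(read[i - 1]);
        int t = (ci >= 0 && ci == base_code(ref_[j - 1])) ? 0 : 1;
        push(rev, t, j - 1, i - 1);
        state = tb & 3u; --i; --j;
      } else if (state == 1) {   // deletion: ref[j-1] against a gap
        push(rev, 2, j - 1, i);
        state = (tb >> 2) & 3u; --j;
      } else {                   // insertion: read[i-1] against a gap
        push(rev, 3, j, i - 1);
        state = (tb >> 4) & 3u; --i;
      }
    }
    res.ok = true;
    res.score = best;
    res.ref_start = j;
    res.ref_end = bj;
    res.ops.assign(rev.rbegin(), rev.rend());
    return res;
  }

  int n() const { return n_; }

private:
  void ensure(int m) {
    size_t need = (size_t) (m + 1) * (size_t) (n_ + 1);
    if (need > cap_) {
      M_.resize(need); D_.resize(need); I_.resize(need); TB_.resize(need);
      cap_ = need;
    }
  }
  // runs are built back-to-front: extend if same type and adjacent
  static void push(std::vector<OpRun>& rev, int type, int ref_pos, int read_pos) {
    if (!rev.empty()) {
      OpRun& last = rev.back();
      bool adj = false;
      if (last.type == type) {
        if (type == 0 || type == 1)
          adj = (last.ref_start == ref_pos + 1 && last.read_start == read_pos + 1);
        else if (type == 2)
          adj = (last.ref_start == ref_pos + 1 && last.read_start == read_pos);
        else
          adj = (last.ref_start == ref_pos && last.read_start == read_pos + 1);
      }
      if (adj) {
        last.ref_start = ref_pos;
        if (type != 2) last.read_start = read_pos;
        ++last.len;
        return;
      }
    }
    OpRun r; r.type = type; r.ref_start = ref_pos; r.len = 1; r.read_start = read_pos;
    rev.push_back(r);
  }

  std::string ref_;
  int n_, match_, mismatch_, open_, ext_;
  std::vector<int> M_, D_, I_;
  std::vector<uint8_t> TB_;
  size_t cap_;
};

// [[Rcpp::export]]
List align_batch_cpp(CharacterVector reads, CharacterVector reads_rc,
                     std::string ref, int match, int mismatch,
                     int gap_open, int gap_ext) {
  const int nr = reads.size();
  if (reads_rc.size() != nr) stop("reads and reads_rc differ in length");
  KmerIndex idx = index_kmers(ref);
  Aligner al(ref, match, mismatch, gap_open, gap_ext);
  const int n = al.n();

  IntegerVector score(nr), ref_start(nr), ref_end(nr);
  IntegerVector orient(nr);          // 0 forward, 1 reverse-complement
  LogicalVector aligned(nr);
  std::vector<int> o_read, o_type, o_rstart, o_len, o_qstart;

  for (int r = 0; r < nr; ++r) {
    std::string fw = as<std::string>(reads[r]);
    std::string rc = as<std::string>(reads_rc[r]);
    const int m = (int) fw.size();
    if (m == 0 || m > n) stop("read %d has length %d (reference is %d bp)", r + 1, m, n);

    std::vector<int> dfw = seed_diagonals(fw, idx);
    std::vector<int> drc = seed_diagonals(rc, idx);
    int lof, hif, lor, hir;
    bool sfw = seed_band(dfw, lof, hif);
    bool src = seed_band(drc, lor, hir);

    AlnResult afw, arc;
    afw.ok = arc.ok = false;
    if (sfw) afw = al.align(fw, lof, hif);
    if (src) arc = al.align(rc, lor, hir);
    if (!sfw && !src) {              // no seeds either way: full matrix
      afw = al.align(fw, -m, n);
      arc = al.align(rc, -m, n);
    }

    const AlnResult* best = 0;
    int ori = 0;
    if (afw.ok && (!arc.ok || afw.score >= arc.score)) { best = &afw; ori = 0; }
    else if (arc.ok) { best = &arc; ori = 1; }

    if (!best) { aligned[r] = false; score[r] = NA_INTEGER; ref_start[r] = NA_INTEGER; ref_end[r] = NA_INTEGER; orient[r] = NA_INTEGER; continue; }
    aligned[r] = true;
    score[r] = best->score;
    ref_start[r] = best->ref_start;
    ref_end[r] = best->ref_end;
    orient[r] = ori;
    for (size_t k = 0; k < best->ops.size(); ++k) {
      const OpRun& op = best->ops[k];
      o_read.push_back(r + 1);
      o_type.push_back(op.type);
      o_rstart.push_back(op.ref_start);
      o_len.push_back(op.len);
      o_qstart.push_back(op.read_start);
    }
  }

  return List::create(
      _["aligned"] = aligned, _["score"] = score, _["orientation"] = orient,
      _["ref_start"] = ref_start, _["ref_end"] = ref_end,
      _["op_read"] = wrap(o_read), _["op_type"] = wrap(o_type),
      _["op_ref_start"] = wrap(o_rstart), _["op_len"] = wrap(o_len),
      _["op_read_start"] = wrap(o_qstart));
}
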