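// Toy ungapped seed-and-extend local aligner: exact word seeding on a
// single strand, two-sided x-drop extension, per-diagonal merging of
// overlapping hits. Fixture-scale stand-in for a genuine local aligner;
// no gapped extension, no e-value statistics.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': case 'a': v[i] = 0; break;
      case 'C': case 'c': v[i] = 1; break;
      case 'G': case 'g': v[i] = 2; break;
      case 'T': case 't': v[i] = 3; break;
      default: v[i] = -1;
    }
  }
  return v;
}

// word codes; -1 where the window contains a non-ACGT base
static std::vector<long> word_codes(const std::vector<int>& v, int word) {
  const long n = (long)v.size() - word + 1;
  std::vector<long> codes(n > 0 ? n : 0, -1);
  if (n <= 0) return codes;
  long code = 0, mask = 1;
  for (int k = 0; k < word; ++k) mask *= 4;
  int bad = 0;
  for (long i = 0; i < (long)v.size(); ++i) {
    code = (code * 4) % mask;
    if (v[i] < 0) { bad = word; } else { code += v[i]; if (bad > 0) --bad; }
    if (i >= word - 1 && bad == 0) codes[i - word + 1] = code;
  }
  return codes;
}

struct Seed { long diag, qpos, spos; };

// [[Rcpp::export]]
List cpp_seed_extend(std::string query, std::string subject, int word,
                     double match, double mismatch, double xdrop,
                     double min_score) {
  std::vector<int> q = encode(query), s = encode(subject);
  const long nq = q.size(), ns = s.size();
  std::vector<long> qc = word_codes(q, word), sc = word_codes(s, word);

  long n_codes = 1;
  for (int k = 0; k < word; ++k) n_codes *= 4;

  // bucket subject word positions by code (counting sort)
  std::vector<long> cnt(n_codes + 1, 0);
  for (long i = 0; i < (long)sc.size(); ++i) if (sc[i] >= 0) ++cnt[sc[i] + 1];
  for (long c = 0; c < n_codes; ++c) cnt[c + 1] += cnt[c];
  std::vector<long> bucket(cnt[n_codes]);
  {
    std::vector<long> fill(cnt.begin(), cnt.end() - 1);
    for (long i = 0; i < (long)sc.size(); ++i)
      if (sc[i] >= 0) bucket[fill[sc[i]]++] = i;
  }

  std::vector<Seed> seeds;
  for (long i = 0; i < (long)qc.size(); ++i) {
    if (qc[i] < 0) continue;
    for (long b = cnt[qc[i]]; b < cnt[qc[i] + 1]; ++b) {
      seeds.push_back({bucket[b] - i, i, bucket[b]});
    }
  }
  std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
    return a.diag != b.diag ? a.diag < b.diag : a.qpos < b.qpos;
  });

  std::vector<long> out_qs, out_qe, out_ss, out_se, out_len, out_mm;
  std::vector<double> out_score;

  long cur_diag = seeds.empty() ? 0 : seeds[0].diag - 1;
  long watermark = -1;  // query end (exclusive) covered on current diagonal
  for (const Seed& sd : seeds) {
    if (sd.diag != cur_diag) { cur_diag = sd.diag; watermark = -1; }
    if (sd.qpos < watermark) continue;
    // seed span scores word matches; extend right from qpos+word
    long q0 = sd.qpos, q1 = sd.qpos + word - 1;
    double score = word * match;
    // right
    {
      double best = score, run = score;
      long bi = q1;
      for (long i = q1 + 1; i < nq && i + sd.diag < ns; ++i) {
        if (q[i] < 0 || s[i + sd.diag] < 0) break;
        run += (q[i] == s[i + sd.diag]) ? match : mismatch;
        if (run > best) { best = run; bi = i; }
        if (best - run > xdrop) break;
      }
      score = best; q1 = bi;
    }
    // left
    {
      double best = score, run = score;
      long bi = q0;
      for (long i = q0 - 1; i >= 0 && i + sd.diag >= 0; --i) {
        if (q[i] < 0 || s[i + sd.diag] < 0) break;
        run += (q[i] == s[i + sd.diag]) ? match : mismatch;
        if (run > best) { best = run; bi = i; }
        if (best - run > xdrop) break;
      }
      score = best; q0 = bi;
    }
    watermark = q1 + 1;
    if (score < min_score) continue;
    long len = q1 - q0 + 1, mm = 0;
    for (long i = q0; i <= q1; ++i) if (q[i] != s[i + sd.diag]) ++mm;
    out_qs.push_back(q0 + 1); out_qe.push_back(q1 + 1);
    out_ss.push_back(q0 + sd.diag + 1); out_se.push_back(q1 + sd.diag + 1);
    out_len.push_back(len); out_mm.push_back(mm); out_score.push_back(score);
  }

  return List::create(_["qstart"] = wrap(out_qs), _["qend"] = wrap(out_qe),
                      _["sstart"] = wrap(out_ss), _["send"] = wrap(out_se),
                      _["length"] = wrap(out_len), _["mismatch"] = wrap(out_mm),
                      _["score"] = wrap(out_score));
}
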