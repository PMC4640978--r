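#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Brute-force nearest vertex. Meshes here are ~5.6k vertices, so the full
// scan is ~31M distance evaluations and runs in tens of milliseconds; a
// spatial index would not pay for itself at this size.
// [[Rcpp::export(name = ".cppClosestVertex")]]
IntegerVector cppClosestVertex(NumericMatrix query, NumericMatrix ref) {
    const int nq = query.nrow(), nr = ref.nrow();
    IntegerVector idx(nq);
    std::vector<double> rx(nr), ry(nr), rz(nr);
    for (int j = 0; j < nr; ++j) {
        rx[j] = ref(j, 0); ry[j] = ref(j, 1); rz[j] = ref(j, 2);
    }
    for (int i = 0; i < nq; ++i) {
        const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
        double best = DBL_MAX; int bj = 0;
        for (int j = 0; j < nr; ++j) {
            const double dx = qx - rx[j], dy = qy - ry[j], dz = qz - rz[j];
            const double d = dx * dx + dy * dy + dz * dz;
            if (d < best) { best = d; bj = j; }
        }
        idx[i] = bj + 1;
    }
    return idx;
}

static inline void closestOnTriangle(const double *p, const double *a,
                                     const double *b, const double *c,
                                     double *out, double *bary) {
    // Ericson, Real-Time Collision Detection, closest point on triangle.
    double ab[3], ac[3], ap[3];
    for (int k = 0; k < 3; ++k) {
        ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k];
    }
    double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
    double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
    if (d1 <= 0.0 && d2 <= 0.0) {
        for (int k = 0; k < 3; ++k) out[k] = a[k];
        bary[0] = 1; bary[1] = 0; bary[2] = 0; return;
    }
    double bp[3];
    for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
        for (int k = 0; k < 3; ++k) out[k] = b[k];
        bary[0] = 0; bary[1] = 1; bary[2] = 0; return;
    }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
        bary[0] = 1 - v; bary[1] = v; bary[2] = 0; return;
    }
    double cp[3];
    for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
    double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
    double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
    if (d6 >= 0.0 && d5 <= d6) {
        for (int k = 0; k < 3; ++k) out[k] = c[k];
        bary[0] = 0; bary[1] = 0; bary[2] = 1; return;
    }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
        double w = d2 / (d2 - d6);
        for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
        bary[0] = 1 - w; bary[1] = 0; bary[2] = w; return;
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
        double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
        bary[0] = 0; bary[1] = 1 - w; bary[2] = w; return;
    }
    double denom = 1.0 / (va + vb + vc);
    double v = vb * denom, w = vc * denom;
    for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
    bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
}

// Closest point on a triangulated surface: nearest vertex first, then exact
// projection onto the triangles incident to that vertex and its 1-ring.
// faces: 1-based m x 3; vtx2tri: list of 1-based incident-triangle indices
// per reference vertex (including the 1-ring's triangles).
// [[Rcpp::export(name = ".cppClosestSurfacePoint")]]
List cppClosestSurfacePoint(NumericMatrix query, NumericMatrix refV,
                            IntegerMatrix faces, List vtx2tri) {
    const int nq = query.nrow(), nr = refV.nrow();
    NumericMatrix point(nq, 3), bary(nq, 3);
    IntegerVector tri(nq);
    NumericVector dist(nq);
    std::vector<double> rx(nr), ry(nr), rz(nr);
    for (int j = 0; j < nr; ++j) {
        rx[j] = refV(j, 0); ry[j] = refV(j, 1); rz[j] = refV(j, 2);
    }
    for (int i = 0; i < nq; ++i) {
        double p[3] = { query(i, 0), query(i, 1), query(i, 2) };
        double best = DBL_MAX; int bj = 0;
        for (int j = 0; j < nr; ++j) {
            const double dx = p[0]-rx[j], dy = p[1]-ry[j], dz = p[2]-rz[j];
            const double d = dx*dx + dy*dy + dz*dz;
            if (d < best) { best = d; bj = j; }
        }
        IntegerVector cand = vtx2tri[bj];
        double bestd = DBL_MAX, bp[3] = {0, 0, 0}, bb[3] = {1, 0, 0};
        int bt = cand.size() ? cand[0] : 1;
        for (int t = 0; t < cand.size(); ++t) {
            const int f = cand[t] - 1;
            double a[3], b[3], c[3], out[3], bc[3];
            const int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1,
                      ic = faces(f, 2) - 1;
            a[0]=refV(ia,0); a[1]=refV(ia,1); a[2]=refV(ia,2);
            b[0]=refV(ib,0); b[1]=refV(ib,1); b[2]=refV(ib,2);
            c[0]=refV(ic,0); c[1]=refV(ic,1); c[2]=refV(ic,2);
            closestOnTriangle(p, a, b, c, out, bc);
            const double dx=p[0]-out[0], dy=p[1]-out[1], dz=p[2]-out[2];
            const double d = dx*dx + dy*dy + dz*dz;
            if (d < bestd) {
                bestd = d; bt = cand[t];
                for (int k = 0; k < 3; ++k) { bp[k] = out[k]; bb[k] = bc[k]; }
            }
        }
        for (int k = 0; k < 3; ++k) { point(i, k) = bp[k]; bary(i, k) = bb[k]; }
        tri[i] = bt;
        dist[i] = std::sqrt(bestd);
    }
    return List::create(_["point"] = point, _["triangle"] = tri,
                        _["bary"] = bary, _["distance"] = dist);
}

// Normal-shooting correspondence: intersect the ray q + t*d (both signs
// of t) with the reference surface and keep up to 3 hits sorted by |t|.
// Candidate triangles come from a 3-ring around the nearest reference
// vertex, falling back to a full scan when nothing is hit (large
// deformations can put the intersection far from the nearest vertex).
// The caller selects among hits (e.g. nearest to a model prediction),
// which disambiguates multiple sheets.
// [[Rcpp::export(name = ".cppRayShoot")]]
List cppRayShoot(NumericMatrix query, NumericMatrix dir, NumericMatrix refV,
                 IntegerMatrix faces, List cand, double tmax,
                 bool fullScan = true) {
    const int nq = query.nrow(), nr = refV.nrow();
    const int K = 3;
    NumericMatrix tval(nq, K), baryAll(nq, 3 * K);
    IntegerMatrix triAll(nq, K);
    IntegerVector nhit(nq);
    std::vector<double> rx(nr), ry(nr), rz(nr);
    for (int j = 0; j < nr; ++j) {
        rx[j] = refV(j, 0); ry[j] = refV(j, 1); rz[j] = refV(j, 2);
    }
    for (int i = 0; i < nq; ++i) {
        const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
        const double dx = dir(i, 0), dy = dir(i, 1), dz = dir(i, 2);
        double best = DBL_MAX; int bj = 0;
        for (int j = 0; j < nr; ++j) {
            const double ex = qx - rx[j], ey = qy - ry[j], ez = qz - rz[j];
            const double d2 = ex * ex + ey * ey + ez * ez;
            if (d2 < best) { best = d2; bj = j; }
        }
        IntegerVector cc = cand[bj];
        double ht[K]; int hf[K]; double hu[K], hv[K];
        int nh = 0;
        for (int pass = 0; pass < (fullScan ? 2 : 1) && nh == 0; ++pass) {
            const int ntest = pass == 0 ? cc.size() : faces.nrow();
            for (int t = 0; t < ntest; ++t) {
                const int f = pass == 0 ? cc[t] - 1 : t;
                const int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1,
                          ic = faces(f, 2) - 1;
                // Moller-Trumbore
                const double e1x = rx[ib]-rx[ia], e1y = ry[ib]-ry[ia],
                             e1z = rz[ib]-rz[ia];
                const double e2x = rx[ic]-rx[ia], e2y = ry[ic]-ry[ia],
                             e2z = rz[ic]-rz[ia];
                const double px = dy*e2z - dz*e2y, py = dz*e2x - dx*e2z,
                             pz = dx*e2y - dy*e2x;
                const double det = e1x*px + e1y*py + e1z*pz;
                if (std::fabs(det) < 1e-12) continue;
                const double inv = 1.0 / det;
                const double sx = qx - rx[ia], sy = qy - ry[ia],
                             sz = qz - rz[ia];
                const double u = (sx*px + sy*py + sz*pz) * inv;
                if (u < -1e-9 || u > 1 + 1e-9) continue;
                const double qxv = sy*e1z - sz*e1y, qyv = sz*e1x - sx*e1z,
                             qzv = sx*e1y - sy*e1x;
                const double v = (dx*qxv + dy*qyv + dz*qzv) * inv;
                if (v < -1e-9 || u + v > 1 + 1e-9) continue;
                const double tt = (e2x*qxv + e2y*qyv + e2z*qzv) * inv;
                if (std::fabs(tt) > tmax) continue;
                // duplicate intersections (shared edges of adjacent
                // triangles) collapse onto one slot
                bool dup = false;
                for (int k = 0; k < nh; ++k)
                    if (std::fabs(ht[k] - tt) < 1e-7) { dup = true; break; }
                if (dup) continue;
                if (nh < K) {
                    ht[nh] = tt; hf[nh] = f + 1; hu[nh] = u; hv[nh] = v;
                    ++nh;
                } else {
                    int worst = 0;
                    for (int k = 1; k < K; ++k)
                        if (std::fabs(ht[k]) > std::fabs(ht[worst]))
                            worst = k;
                    if (std::fabs(tt) < std::fabs(ht[worst])) {
                        ht[worst] = tt; hf[worst] = f + 1;
                        hu[worst] = u; hv[worst] = v;
                    }
                }
            }
        }
        // sort kept hits by |t|
        for (int a = 0; a < nh; ++a)
            for (int b = a + 1; b < nh; ++b)
                if (std::fabs(ht[b]) < std::fabs(ht[a])) {
                    std::swap(ht[a], ht[b]); std::swap(hf[a], hf[b]);
                    std::swap(hu[a], hu[b]); std::swap(hv[a], hv[b]);
                }
        nhit[i] = nh;
        for (int k = 0; k < nh; ++k) {
            tval(i, k) = ht[k];
            triAll(i, k) = hf[k];
            baryAll(i, 3 * k) = 1 - hu[k] - hv[k];
            baryAll(i, 3 * k + 1) = hu[k];
            baryAll(i, 3 * k + 2) = hv[k];
        }
    }
    return List::create(_["t"] = tval, _["triangle"] = triAll,
                        _["bary"] = baryAll, _["nhit"] = nhit);
}
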