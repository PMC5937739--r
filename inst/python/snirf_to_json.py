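"""Read an SNIRF (HDF5) file and emit a flat JSON payload on stdout.

Output fields: wavelengths, time_step, n_channels, n_wavelengths,
n_samples, channels (source/detector per channel), data_flat (channels x
wavelengths x samples flattened in Fortran order).
"""
import json
import sys

try:
    import h5py
    import numpy as np
except Exception as exc:  # pragma: no cover
    print(json.dumps({"error": f"python dependencies unavailable: {exc}"}))
    sys.exit(0)


def main(path):
    with h5py.File(path, "r") as f:
        nirs = f["nirs"] if "nirs" in f else f["/nirs1"]
        data = nirs["data1"]
        ts = np.asarray(data["dataTimeSeries"])  # time x measurements
        time = np.asarray(data["time"]).ravel()
        if time.size >= 2:
            step = float(np.median(np.diff(time)))
        else:
            step = float(time[0]) if time.size else 1.0
        wavelengths = np.asarray(nirs["probe"]["wavelengths"]).ravel()

        meas = []
        for key in sorted(k for k in data.keys() if k.startswith("measurementList")):
            ml = data[key]
            meas.append((int(np.asarray(ml["sourceIndex"])),
                         int(np.asarray(ml["detectorIndex"])),
                         int(np.asarray(ml["wavelengthIndex"]))))
        if not meas:
            return {"error": "no measurementList entries"}
        pairs = sorted({(s, d) for s, d, _ in meas})
        n_wl = len(wavelengths)
        n_samp = ts.shape[0]
        cube = np.full((len(pairs), n_wl, n_samp), np.nan)
        for col, (s, d, w) in enumerate(meas):
            cube[pairs.index((s, d)), w - 1, :] = ts[:, col]
        if np.isnan(cube).any():
            return {"error": "incomplete wavelength coverage across channels"}
        return {
            "wavelengths": [float(w) for w in wavelengths],
            "time_step": step,
            "n_channels": len(pairs),
            "n_wavelengths": n_wl,
            "n_samples": int(n_samp),
            "channels": [{"source": s, "detector": d} for s, d in pairs],
            "data_flat": cube.flatten(order="F").tolist(),
        }


if __name__ == "__main__":
    try:
        out = main(sys.argv[1])
    except Exception as exc:
        out = {"error": str(exc)}
    print(json.dumps(out))
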