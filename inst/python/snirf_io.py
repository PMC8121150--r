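"""Minimal SNIRF (HDF5) continuous-wave I/O helper.

Called by the R package through system2(); exchanges the intensity block
as CSV and the metadata as JSON. Only the continuous-wave amplitude
subset of SNIRF (dataType 1) is supported.

Usage:
  python snirf_io.py write META.json DATA.csv OUT.snirf
  python snirf_io.py read  IN.snirf  META.json DATA.csv
"""
import json
import sys

import h5py
import numpy as np


def _str(ds):
    v = ds[()]
    if isinstance(v, bytes):
        return v.decode()
    if isinstance(v, np.ndarray) and v.dtype.kind in "SO":
        return v.item().decode()
    return str(v)


def write(meta_path, data_path, out_path):
    meta = json.load(open(meta_path))
    data = np.loadtxt(data_path, delimiter=",", skiprows=1, ndmin=2)
    fs = float(meta["sampling_rate"])
    wavelengths = [float(w) for w in meta["wavelengths"]]
    n_channels = int(meta["n_channels"])
    nt = data.shape[0]
    assert data.shape[1] == 2 * n_channels
    with h5py.File(out_path, "w") as f:
        f.create_dataset("formatVersion", data="1.0")
        nirs = f.create_group("/nirs")
        tags = nirs.create_group("metaDataTags")
        tags.create_dataset("SubjectID", data=str(meta.get("subject", "")))
        tags.create_dataset("MeasurementDate", data="unknown")
        tags.create_dataset("MeasurementTime", data="unknown")
        tags.create_dataset("LengthUnit", data="cm")
        tags.create_dataset("TimeUnit", data="s")
        tags.create_dataset("FrequencyUnit", data="Hz")
        probe = nirs.create_group("probe")
        probe.create_dataset("wavelengths", data=np.asarray(wavelengths))
        pos = np.zeros((n_channels, 2))
        pos[:, 0] = np.arange(n_channels)
        probe.create_dataset("sourcePos2D", data=pos)
        probe.create_dataset("detectorPos2D", data=pos + 0.5)
        d1 = nirs.create_group("data1")
        d1.create_dataset("dataTimeSeries", data=data)
        d1.create_dataset("time", data=np.arange(nt) / fs)
        col = 0
        for ch in range(1, n_channels + 1):
            for wl in (1, 2):
                ml = d1.create_group("measurementList%d" % (col + 1))
                ml.create_dataset("sourceIndex", data=ch)
                ml.create_dataset("detectorIndex", data=ch)
                ml.create_dataset("wavelengthIndex", data=wl)
                ml.create_dataset("dataType", data=1)
                ml.create_dataset("dataTypeIndex", data=1)
                col += 1


def read(in_path, meta_path, data_path):
    with h5py.File(in_path, "r") as f:
        if "nirs" not in f or "data1" not in f["nirs"]:
            raise SystemExit("format error: no /nirs/data1 group")
        d1 = f["nirs/data1"]
        if "dataTimeSeries" not in d1:
            raise SystemExit("format error: no dataTimeSeries")
        data = np.asarray(d1["dataTimeSeries"], dtype=float)
        if data.size == 0:
            raise SystemExit("format error: empty dataTimeSeries")
        time = np.asarray(d1["time"], dtype=float)
        wavelengths = np.asarray(f["nirs/probe/wavelengths"], dtype=float)
        if wavelengths.size != 2:
            raise SystemExit(
                "unsupported format: need exactly 2 wavelengths, got %d"
                % wavelengths.size)
        mls = sorted((k for k in d1 if k.startswith("measurementList")),
                     key=lambda k: int(k[len("measurementList"):]))
        if len(mls) != data.shape[1]:
            raise SystemExit("format error: measurementList/data mismatch")
        chans, wlidx = [], []
        for k in mls:
            ml = d1[k]
            if int(ml["dataType"][()]) != 1:
                raise SystemExit(
                    "unsupported format: non-continuous-wave dataType %d"
                    % int(ml["dataType"][()]))
            chans.append((int(ml["sourceIndex"][()]),
                          int(ml["detectorIndex"][()])))
            wlidx.append(int(ml["wavelengthIndex"][()]))
        pairs = list(dict.fromkeys(chans))  # channel ids in file order
        n_channels = len(pairs)
        out = np.zeros((data.shape[0], 2 * n_channels))
        for j, (pair, wl) in enumerate(zip(chans, wlidx)):
            ch = pairs.index(pair)
            out[:, 2 * ch + (wl - 1)] = data[:, j]
        if time.size >= 2:
            fs = 1.0 / float(np.median(np.diff(time)))
        else:
            fs = 1.0
        subject = ""
        tags = f["nirs"].get("metaDataTags")
        if tags is not None and "SubjectID" in tags:
            subject = _str(tags["SubjectID"])
    json.dump({"sampling_rate": fs,
               "wavelengths": [float(w) for w in wavelengths],
               "n_channels": n_channels, "subject": subject},
              open(meta_path, "w"))
    header = ",".join("c%dw%d" % (c, w)
                      for c in range(1, n_channels + 1) for w in (1, 2))
    np.savetxt(data_path, out, delimiter=",", header=header, comments="")


if __name__ == "__main__":
    mode = sys.argv[1]
    if mode == "write":
        write(*sys.argv[2:5])
    elif mode == "read":
        read(*sys.argv[2:5])
    else:
        raise SystemExit("unknown mode: %s" % mode)
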