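#!/usr/bin/env python
"""Single-file relational (SQLite) project store bridge.

The R side exchanges tables as full-precision CSV ("%.17g" for doubles,
which round-trips IEEE 754 exactly); this script moves them in and out of
one SQLite database file. Column classes are kept in a _schema table so a
loaded table reproduces the saved one bit-identically.

Usage:
  storebridge.py init   <db> <schema_version>
  storebridge.py meta   <db>                      -> JSON on stdout
  storebridge.py tables <db>                      -> JSON list on stdout
  storebridge.py write  <db> <table> <csv> <classes-json>
  storebridge.py read   <db> <table> <csv-out>    -> classes JSON on stdout
  storebridge.py drop   <db> <table>
"""

import csv
import json
import sqlite3
import sys


def connect(path):
    con = sqlite3.connect(path)
    con.execute("CREATE TABLE IF NOT EXISTS _meta (key TEXT PRIMARY KEY,"
                " value TEXT)")
    con.execute("CREATE TABLE IF NOT EXISTS _schema (tbl TEXT PRIMARY KEY,"
                " classes TEXT)")
    return con


def sql_type(cls):
    return {"numeric": "REAL", "integer": "INTEGER",
            "logical": "INTEGER"}.get(cls, "TEXT")


def cmd_init(db, version):
    con = connect(db)
    con.execute("INSERT OR REPLACE INTO _meta VALUES ('schema_version', ?)",
                (version,))
    con.commit()


def cmd_meta(db):
    con = connect(db)
    rows = con.execute("SELECT key, value FROM _meta").fetchall()
    json.dump(dict(rows), sys.stdout)


def cmd_tables(db):
    con = connect(db)
    rows = con.execute(
        "SELECT name FROM sqlite_master WHERE type='table'"
        " AND name NOT LIKE '\\_%' ESCAPE '\\' ORDER BY name").fetchall()
    json.dump([r[0] for r in rows], sys.stdout)


def cmd_write(db, table, csv_path, classes_json):
    classes = json.loads(classes_json)
    con = connect(db)
    with open(csv_path, newline="") as fh:
        reader = csv.reader(fh)
        header = next(reader)
        cols = ", ".join('"%s" %s' % (c, sql_type(classes[c]))
                         for c in header)
        con.execute('DROP TABLE IF EXISTS "%s"' % table)
        con.execute('CREATE TABLE "%s" (%s)' % (table, cols))
        ins = 'INSERT INTO "%s" VALUES (%s)' % (
            table, ", ".join("?" * len(header)))

        def conv(val, cls):
            if val == "NA":
                return None
            if cls == "numeric":
                return float(val)
            if cls in ("integer", "logical"):
                return int(val)
            return val

        for row in reader:
            con.execute(ins, [conv(v, classes[c])
                              for v, c in zip(row, header)])
    con.execute("INSERT OR REPLACE INTO _schema VALUES (?, ?)",
                (table, classes_json))
    con.commit()


def cmd_read(db, table, csv_out):
    con = connect(db)
    row = con.execute("SELECT classes FROM _schema WHERE tbl = ?",
                      (table,)).fetchone()
    if row is None:
        sys.stderr.write("no such table: %s\n" % table)
        sys.exit(3)
    classes = json.loads(row[0])
    cur = con.execute('SELECT * FROM "%s"' % table)
    header = [d[0] for d in cur.description]

    def fmt(val, cls):
        if val is None:
            return "NA"
        if cls == "numeric":
            return repr(float(val))
        return str(val)

    with open(csv_out, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(header)
        for rec in cur:
            w.writerow([fmt(v, classes[c]) for v, c in zip(rec, header)])
    json.dump(classes, sys.stdout)


def cmd_drop(db, table):
    con = connect(db)
    con.execute('DROP TABLE IF EXISTS "%s"' % table)
    con.execute("DELETE FROM _schema WHERE tbl = ?", (table,))
    con.commit()


def main():
    cmd = sys.argv[1]
    {"init": cmd_init, "meta": cmd_meta, "tables": cmd_tables,
     "write": cmd_write, "read": cmd_read, "drop": cmd_drop}[cmd](
        *sys.argv[2:])


if __name__ == "__main__":
    main()
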