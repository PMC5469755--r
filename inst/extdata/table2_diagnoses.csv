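# Transcription of the published molecular-diagnosis table for the
# Niphargus stygius complex: 8 newly described species and 9 reference
# specimens of previously described species (17 rows). Diagnosis position
# lists are verbatim, including typographic anomalies of the printed
# table ("1229-", "1032,", "13338 T") which parse_diagnosis() flags in
# validation mode. "-" after a gap position denotes a gap in alignment.
species,status,zoobank,worms,type_locality,country,voucher,diagnosis
Niphargus chagankae,new,4DF5BD7A-B343-4354-AC65-F7FFFA829123,988191,"Cave Čaganka, Poljanska gora, Črnomelj, Slovenia",Slovenia,NB792,"28S: - | COI: 228 G, 262 T, 264 A, 300 A | ITS: 98 G, 540 C, 877 A, 1027 T, 1050 G, 1084 C, 1152 A, 1172 G, 1178 G, 1200 -, 1201 -, 1202 -, 1204 -, 1209 -, 1211 -, 1212 -, 1213 -, 1217 -, 1218 -, 1221 -, 1222 -, 1223 -, 1229-, 1233 -, 1235 -, 1238 -, 1241 -, 1638 T, 1682 T, 1726 C, 1727 T, 1728 C, 1737 T, 1741 T, 1898 C, 2055 T, 2065 A, 2070 -"
Niphargus cvajcki,new,A6B6A0BC-20BC-4109-BAAA-72588484BC5A,988197,"Cave Šolnovo brezno, Prevole, Žužemberk, Slovenia",Slovenia,NB915,"28S: 74 G, 78 C, 81 T, 136 -, 160 A, 196 T, 203 G, 209 A | COI: 3 T, 300 G, 303 G, 360 T, 411 T, 418 A, 419 G, 537 G | ITS: 62 A, 94 T, 124 C, 209 G, 462 T, 613 C, 707 C, 709 -, 712 A, 715 C, 794 C, 809 G, 835 C, 836 G, 840 C, 846 A, 868 G, 873 A, 881 T, 888 G, 897 C, 902 C, 906 A, 1013 G, 1015 C, 1032, 1038 A, 1044 T, 1054 C, 1055 A, 1056 G, 1062 T, 1162 T, 1166 G, 1171 A, 1172 T, 1220 G, 1242 T, 1250 G, 1251 C, 1253 T, 1260 G, 1261 G, 1273 G, 1278 A, 1288 C, 1293 G, 1301 C, 1305 C, 1307 T, 1310 A, 1314 G, 1315 T, 1316 A, 1318 T, 1327 G, 1331 A, 1333 C, 1334 C, 1335 G, 1336 C, 13338 T, 1339 C, 1340 T, 1343 G, 1345 G, 1346 T, 1353 A, 1354 C, 1355 T, 1360 G, 1362 G, 1364 A, 1367 T, 1369 C, 1371 A, 1377 A, 1380 T, 1382 G, 1384 A, 1385 A, 1387 A, 1388 C, 1392 A, 1394 C, 1395 C, 1397 C, 1398 T, 1399 T, 1401 A, 1402 A, 1409 G, 1428 A, 1431 T, 1434 A, 1440 T, 1443 G, 1446 T, 1447 A, 1454 C, 1455 A, 1472 G, 1479 C, 1481 T, 1497 G, 1499 C, 1533 T, 1546 G, 1547 T, 1551 G, 1552 T, 1554 G, 1557 G, 1563 A, 1564 T, 1567 A, 1589 G, 1590 G, 1595 T, 1600 G, 1612 G, 1644 G, 1652 T, 1655 G, 1668 G, 1673 A, 1680 G, 1688 G, 1690 T, 1697 C, 1702 C, 1706 A, 1813 G, 1832 A, 1835 T, 1838 A, 1844 T, 1849 T, 1850 A, 1857 C, 1858 A, 1859 G, 1864 A, 1865 T, 1879 G, 1888 T, 1894 C, 2032 C, 2033 T, 2034 G, 2037 T, 2045 A, 2046 G, 2048 T, 2080 A, 2099 T"
Niphargus goricae,new,A0A0651F-685D-45D4-9477-5E44408D4CF3,988195,"Water well by the house Fram 119, Fram, Maribor, Slovenia",Slovenia,NA085,"28S: 113 A, 115 C, 147 T, 148 C, 149 C, 168 A, 176 T, 179 A, 182 A, 185 T, 200 A, 203 T, 205 C, 207 G, 208 A, 210 G, 269 G, 312 T, 341 C, 344 G, 346 T, 362 T, 451 G, 456 A, 460 T, 491 C, 532 T, 535 A, 573 C, 722 C | COI: 204 C, 375 C, 402 C, 408 G, 441 C, 456 G | ITS: 159 A, 161 C, 162 A, 165 G, 186 T, 213 A, 420 -, 444 G, 445 C, 504 C, 506 G, 519 G, 590 -, 605 C, 619 G, 706 C, 707 T, 708 A, 710 C, 711 A, 717 A, 737 A, 829 A, 839 G, 842 T, 843 C, 851 A, 856 T, 857 A, 1064 G, 1066 T, 1068 T, 1071 T, 1086 T, 1102 C, 1131 G, 1156 -, 1189 T, 1232 C, 1245 T, 1610 T, 1611 T, 1614 A, 1617 C, 2061 A, 2062 C, 2066 T, 2079 G, 2081 T, 2090 C, 2099 C, 2101 G, 2102 G, 2104 A"
Niphargus gottscheeanensis,new,1EEEF2DC-8016-40CE-AB83-3E142905EAB2,988192,"Cave Željnske jame, Željne, Kočevje, Slovenia",Slovenia,NB488,"28S: 182 T, 212 A | COI: 79 G, 381 G | ITS: 1040 G, 1041 T, 1175 C, 2005 A"
Niphargus iskae,new,840AD88E-59E9-4969-ABBE-C4EFEB8D02D9,988194,"Spring on the foothill of Mačji rep, Škrabče, Nova vas, Slovenia",Slovenia,NC087,"28S: na | COI: 138 C, 318 T, 360 C, 402 A, 466 G, 470 C, 482 C, 491 G | ITS: na"
Niphargus kapelanus,new,10A49E2A-C93C-4114-A6EF-54374FE89AE1,988196,"Cave špilja pod Mačkovom dragom, Bjelolasica, Ogulin, Croatia",Croatia,NB625,"28S: 770 G | COI: 75 G, 216 A, 342 A, 345 C, 355 A, 435 A | ITS: na"
Niphargus kordunensis,new,2A2EBA04-D1C8-4024-A1B0-D9BBE0E93CFD,988190,"Matešička špilja, Matešići, Slunj, Croatia",Croatia,NB623,"28S: 128 C, 131 A, 142 T, 145 T, 146 C, 153 C, 156 A, 220 A, 249 C, 676 T, 769 A | COI: na | ITS: na"
Niphargus malagorae,new,333C1C2D-DF19-4B13-826D-C57782EF2864,988193,"Cave Mivčje jama, Gornje Lepovčje, Ribnica, Slovenia",Slovenia,NB858,"28S: 472 A | COI: 237 G, 432 C, 495 C, 555 C | ITS: 75 T, 77 G, 79 T, 82 A, 127 C, 582 T, 587 A, 624 -, 625 -, 632 C, 635 G, 643 A, 851 G, 881 A, 885 G, 886 T, 887 A, 943 T, 1040 C, 1075 G, 1076 T, 1078 T, 1089 C, 1112 G, 1117 G, 1122 C, 1125 -, 1126 T, 1129 A, 1133 T, 1135 G, 1137 G, 1214 G, 1224 T, 1225 A, 1248 C, 1261 T, 1307 G, 1335 A, 1347 T, 1436 C, 1457 A, 1460 G, 1461 A, 1462 G, 1466 G, 1474 T, 1476 A, 1501 A, 1506 C, 1508 A, 1509 G, 1510 C, 1512 C, 1514 A, 1515 G, 1517 C, 1522 A, 1527 G, 1616 T, 1617 A, 1637 A, 1652 A, 1743 T, 1750 A, 1790 T, 1840 C, 1878 T, 1881 T, 1883 A, 1900 A, 1902 C, 1951 T, 2014 T, 2015 A, 2035 A, 2053 A, 2098 C"
Niphargus brachytelson,reference,,,"Lukova jama pri Zdihovem, Zdihovo, Morava, Slovenia",Slovenia,NA071,"28S: 471 C, 472 T | COI: 345 A, 351 C, 481 C, 495 T | ITS: na"
Niphargus hadzii,reference,,,"Springs of Ljubljanica river, Slovenia",Slovenia,NA082,"28S: 181 C | COI: 297 G, 491 C | ITS: na"
Niphargus karamani,reference,,,"well near Miljana, on a riverbank of Sotla, Podčetrtek, Slovenia",Slovenia,NB933,"28S: na | COI: 108 G, 390 A, 529 G | ITS: na"
Niphargus kenki,reference,,,"well near Miljana, on a riverbank of Sotla, Podčetrtek, Slovenia",Slovenia,NA087,"28S: 815 T, 819 A | COI: 482 A, 552 C | ITS: 1140 C, 1141 T, 1145 -, 1181 T"
Niphargus likanus,reference,,,"Cave system Đula - Medvednica, Ogulin, Ogulin, Croatia",Croatia,NB917,"28S: 107 G, 112 C, 170 A, 183 A, 238 T, 516 T, 517 A, 520 T, 521 G, 522 C, 523 A, 524 A, 525 A, 526 A, 527 A, 530 G, 819 T | COI: 276 C, 333 C, 438 C | ITS: 96 T, 254 T, 339 G, 357 T, 371 T, 509 -, 512 T, 513 T, 794 A, 832 T, 887 T, 1097 A, 1116 G, 1656 T, 1915 C, 1918 C, 1924 G, 1926 T, 2291 T, 2348 G, 2376 A"
Niphargus novomestanus,reference,,,"Spring in Prečna, Prečna, Novo mesto, Slovenia",Slovenia,NA131,"28S: 198 T, 469 A | COI: 165 G | ITS: 152 G, 229 A, 486 A, 962 T, 1023 A, 1289 T, 1419 A, 1684 T, 1762 T, 1823 A, 2064 T"
Niphargus podpecanus,reference,,,"Cave Podpeška jama, Podpeč, Videm, Slovenia",Slovenia,NA101,"28S: 172 C, 387 T, 710 T, 731 A, 766 C | COI: 333 G, 423 A, 483 A | ITS: 775 T, 842 A, 849 A, 947 C, 989 C, 1000 A, 1147 A, 1149 T, 1177 G, 1179 A, 1197 T, 1247 G, 1337 A, 1391 A, 1434 T, 1458 C, 1500 C, 1512 A, 1519 G, 1522 T, 1540 A, 1542 T, 1549 C, 1569 G, 1570 A, 1589 T, 1648 A, 1733 A, 1789 C, 1800 A, 1838 T, 1899 A, 1945 A, 1957 G, 1959 C, 1988 T, 1998 T"
Niphargus spoeckeri,reference,,,"Cave Črna jama, Veliki otok, Postojna, Slovenia",Slovenia,NA108,"28S: na | COI: 111 G, 198 G, 318 G, 453 G | ITS: na"
Niphargus zagrebensis,reference,,,"Vicinity of Zagreb, Croatia",Croatia,NA117,"28S: na | COI: 66 G, 123 G | ITS: 126 C, 132 T, 798 C, 828 A, 830 A, 831 C, 842 G, 882 T, 897 A, 909 T, 910 G, 924 T, 935 C, 936 A, 945 C, 948 A, 949 C, 952 G, 954 C, 958 A, 959 A, 961 A, 989 G, 1011 A, 1012 T, 1014 A, 1015 T, 1018 G, 1024 C, 1030 G, 1092 C, 1095 G, 1137 T, 1149 A, 1152 G, 1230 C, 1239 G, 1282 T, 1287 G, 1289 A, 1290 C, 1295 T, 1296 G, 1297 C, 1299 G, 1301 A, 1309 G, 1314 T, 1315 A, 1322 A, 1326 A, 1337 C, 1410 A, 1416 C, 1417 G, 1420 C, 1423 A, 1470 C, 1471 A, 1491 T, 1511 A, 1542 A, 1544 A, 1562 G, 1597 C, 1599 T, 1634 G, 1635 A, 1636 A, 1638 C, 1677 T, 1682 G, 1684 A, 1685 C, 1691 T, 1692 G, 1693 C, 1695 G, 1697 A, 1705 G, 1708 T, 1709 G, 1710 T, 1711 A, 1716 A, 1718 A, 1722 A, 1725 G, 1733 C, 1744 G, 1797 G, 1798 C, 1814 A, 1820 C, 1821 G, 1824 C, 1827 A, 1872 C, 1875 T, 1876 G, 1877 C, 1878 A, 1898 T, 1918 A, 1929 T, 1949 A, 1950 A, 1995 C, 1997 T, 2009 A, 2010 G, 2013 G, 2015 C, 2017 G, 2018 C, 2019 A, 2047 A, 2049 A, 2074 A, 2100 C"
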