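2L	100	A	108:2:0:0:0:0	57:22:0:0:0:0	7:83:0:0:0:0	98:9:0:0:0:0
2R	100	A	93:10:0:0:0:0	64:27:0:0:0:0	7:96:0:0:0:0	72:14:0:0:0:0
3L	100	C	0:8:91:0:0:0	0:43:41:0:0:0	0:56:8:0:0:0	0:24:69:0:0:0
3R	100	G	0:4:0:87:0:0	0:13:0:84:0:0	0:77:0:5:0:0	0:25:0:58:0:0
X	100	G	0:4:0:87:0:0	0:28:0:81:0:0	0:103:0:9:0:0	0:3:0:84:0:0
2L	200	G	0:8:0:82:0:0	0:22:0:74:0:0	0:90:0:6:0:0	0:18:0:67:0:0
2R	200	G	0:0:1:81:0:0	0:0:42:35:0:0	0:0:44:42:0:0	0:0:0:85:0:0
3L	200	G	0:0:1:84:0:0	0:0:34:46:0:0	0:0:47:42:0:0	0:0:2:86:0:0
3R	200	T	0:88:0:2:0:0	0:53:0:54:0:0	0:54:0:50:0:0	0:83:0:0:0:0
X	200	A	76:0:0:0:0:0	39:0:0:40:0:0	52:0:0:40:0:0	111:0:0:0:0:0
2L	300	C	0:3:96:0:0:0	0:51:41:0:0:0	0:41:43:0:0:0	0:0:104:0:0:0
2R	300	T	0:99:0:0:0:0	0:41:50:0:0:0	0:50:43:0:0:0	0:94:0:0:0:0
3L	300	C	0:0:79:21:0:0	0:0:72:8:0:0	0:0:64:16:0:0	0:0:73:7:0:0
3R	300	A	50:29:0:0:0:0	46:39:0:0:0:0	39:45:0:0:0:0	58:26:0:0:0:0
X	300	G	0:0:10:88:0:0	0:0:9:69:0:0	0:0:13:77:0:0	0:0:11:72:0:0
2L	400	T	10:72:0:0:0:0	17:75:0:0:0:0	6:92:0:0:0:0	24:74:0:0:0:0
2R	400	C	35:0:69:0:0:0	28:0:62:0:0:0	26:0:61:0:0:0	23:0:71:0:0:0
3L	400	G	0:0:8:59:0:0	0:0:20:65:0:0	0:0:10:74:0:0	0:0:14:75:0:0
3R	400	G	0:0:19:75:0:0	0:0:27:67:0:0	0:0:22:65:0:0	0:0:34:55:0:0
X	400	G	0:0:34:57:0:0	0:0:45:49:0:0	0:0:15:45:0:0	0:0:10:89:0:0
2L	500	G	0:0:40:47:0:0	0:0:44:45:0:0	0:0:25:64:0:0	0:0:37:44:0:0
2R	500	C	0:0:82:18:0:0	0:0:68:18:0:0	0:0:79:20:0:0	0:0:83:26:0:0
3L	500	C	3:0:93:0:0:0	0:0:80:0:0:0	1:0:81:0:0:0	12:0:79:0:0:0
3R	500	A	86:13:0:0:0:0	88:6:0:0:0:0	92:5:0:0:0:0	77:7:0:0:0:0
X	500	G	36:0:0:68:0:0	41:0:0:45:0:0	15:0:0:73:0:0	51:0:0:34:0:0
2L	600	C	0:0:76:42:0:0	0:0:47:32:0:0	0:0:60:39:0:0	0:0:78:8:0:0
2R	600	T	0:76:29:0:0:0	0:75:18:0:0:0	0:68:15:0:0:0	0:87:14:0:0:0
3L	600	A	89:16:0:0:0:0	75:16:0:0:0:0	74:8:0:0:0:0	109:0:0:0:0:0
3R	600	A	52:33:0:0:0:0	60:20:0:0:0:0	60:40:0:0:0:0	89:20:0:0:0:0
X	600	T	35:49:0:0:0:0	33:47:0:0:0:0	24:64:0:0:0:0	26:69:0:0:0:0
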