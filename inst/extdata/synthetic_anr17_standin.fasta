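>O75179 SYNTHETIC stand-in for human ANR17 (ankyrin repeat domain 17), not the real sequence
SWVVLPIRKRQYPDMVDMPNIMQYIFGQSNDEMYCRFNRREWYNSRCHTSFRDSYSERWT
CGFLLQGNGHFPQPDLHKCMMYDRYQVRFQRKVQVFTRTPTMHQYNGHRVCPDRGSSKPT
CCWWGFCDNKSRWEPGSPGSNNFHAGLICCMRFQIEFCCLHKYKFIFPWDGMRCRYVPRS
RGAESFWRCIETLSCHLRHKLIWWPQSCGLGRPIEHCATVFGCARVLMYSKNHYVMRAEE
AHVGRAIFGFMQEFSFQMFSFPEKYICAKVQYQEAWGWGSIMTTDEIRSWQMLAYIVFEY
LAYGWKSTVDFFLNEGRTTMRAIHREPLWNDCISPDTLHTKQWYHKFKAWCGCVHPIISE
MVKSTAHYFWTLHDHWFSDHFEVHMKVGRCQLVGTLPDSTISMRMGCSNIYDVCSYIFRY
PKAINIIAFCMGSKEQMKCSMFQAIWEKHNFQEVVSVAGTLVFMTNTGVPLMCEWMMDKY
SIVMPHCIYFMYPGDCAAPNSRPWWHDQPCYTKTTIWNDSHPCRVVNLDTTSVTHIIQMR
WGANVCKYMQYLTRAGPVIGWYMHDQSWSARRPNTVQSVNQEVDDLCQCRWCFPNRCCEG
ITFPNCLQAQKPPEVVDLSQLNDIKWNLWKSAWMPEYNTCKVVEVAKRCPCDWHFLKPYR
ETCEAPAHGAMKQSGHMQCCMDDINILLMLRWCCQIVIPLTRCCTADYRLHMIMRGKVTN
FFVSMTQYHCWGRYIPPSSRPKIDHWVFMCNSYEAQPNMDSEWPDVYTFCPTNYTNCETP
CCTEQRSTSTSNKGALERHESTFIRQPLGAQQWGMLFGSLQYTELQPMFQSSGNDSPIKD
TLYSDLWYCNHDKFAYRDCIPNQHQWWLHAKQIGTRLCMDFGCAGRTDNRAFLCIALTHR
WDNPAAFWRHPGACVGCNQKSRERMFSIVRYISKGHWYCSDEIIYPLDIEYYSYFEVDDG
GMRAHYVCIGVIPFFIKCVWTMTGRTPQSIDAGWEMLEIPYLWHIAQSGCTSDENFATKS
YASNCIPQLVIQANYKLRPWGNETWWMCNDMNKVMLMLICYCIKTCKYSEVAGSMSYETA
CQEGMDMFQTDPIPWWMGKGKTDALFDWNTSLINKTQEEDTAAVEGEEHWDMEPQQTSAT
WIMCAVVEWICCSPSECVDLDTVCNVCTQFYMVGCHTMTQDMHQIMCQMPAFAMWEGMPY
RHDLLYTYFYPTWHAPQNHEKHSAWSQNMKKIEKQCYHDHLQGQMMHDSDVVPNEKMKQI
NTWAALDRGPCANHWFYSHTIFKMFWTRLCEQTTEPDFYKVAHYKSTGCIWYPENPHRHE
DQKFYDWPSEKEDDIEQFERPDYHIYFVRGKRGFGSNVDILYGLFNDYAGPIDLSVKYCM
FWVARNHHTCWRGFDWSGHNETAPAWRFEGRQVAYVNKQKACLCYVAAREWWFPDSVLNN
NYKPRHCECLKKDIPNSNNMQIYWGDIFWIRRERDVHQYFKARHQQIHHHCGTEYAWVGA
DSYAPLKYGKNLECSQTQDDQHKKKHFKPNPERYWRLEYSCVSGGCAKTINDEPGYFPSN
EVQCWWLQSMLLQGDLEPHSVVCFNSLLPGPYNKCPLWKNAFPNQGWVCGMDEVYNHIWV
IVAKFITCIQQIIGGWCQWNLTDGVFVWHTCLAPSKYRPWWCHTIHLDCTMHFVLIERLE
WNERHYDQARGHDDLIKQEACPDPPIHNCDWVRVICWGKLNVLTERVDRHEKRQVNIIKQ
EIIGEKIIHESVVCYTHWCCPCGERGNPNNVQERRFIMYMMPNFGYEIHKSAGMNWIRHV
ANLQCDHKTMKNFPPWHEVPCGQGQCDWFRVGRWEYWVNIYAFNAPHWNDVNEGWMWMEG
RWRRPFMQAQNRYFEIDCGHSHGDSWILWGTLTNADSMCPLCMGHLMRSSGDGPTFQFDC
MGSNFSFFVNGNIAYHNPMTSVFYGRYVREPECPVDYKPAIHHCANDLDIEAMFCDVCEY
WDYDRPRMRIVEMVPLWSSDAYQNTCGKHGSGIHNCWSSYMIRRLSWQIWIESMDKHFTR
IGMCDVKARQIYSGNPVERMSKHVNFVQGFHEDDQCAVYRWHNPLNHPNMAYKAGVMWEM
SRGGFYWIWHARFQCARRVKYWTEDGGTTGLCAKKKIHGNLADILCLYNLLKMFKCDQGR
YAPWRWDIFDKWDTDMLSCIKNIRDGVHAWHREMGFNPEYADPMNVGWTRTIRSKTPEIT
IKTWGTDWKWKMSFLLPFFYEDLCNATITHNWDYKVEWIDMSSYEQRKNDFWGKYCCTLV
VYGTSTNFNKSVNAGGHVTVKLMFNNKTEPKHANQQHNDVYNQWVLHAIWYADHTKSPWE
SETLWSPEQPYMSLPVALCEIKSTMQALTLFCCAILMVKECHCCHDSSECPKRVDQAAYV
NGNFQHDRHIRCCNVLEAWLYDSYPNRKGLDPKYTAEAINNCTGQMWMPHMDGAVQDSQL
DWNNAYFDWETREVILNELQTKRVCADNSHSGPHQKDGHTDITFGHPEVMFCQCGHGAMM
CPFAVRECDWLLPPTCNANDHPYKVHDYAGHKGCYTEGFQFCFDRRRRMLMACGGFDRNI
VECGIVTSNQEIDTGCVRRRNWM
>Q99NH0 SYNTHETIC stand-in for mouse Ankrd17 ortholog, not the real sequence
SWVVLPPRKRQYCDMVDMPNIMQYIFGQSNDEMYCRFNRREWYNSRCHTSFRDSYSERWT
CGFLLQGNGHFPDPDLHKCMLDDRYQVRFQRKVQVFTRTPFMHQYNGHRVCPDRGSSKPT
CCWWYFCDNKSRWEPQSPGSNNFHAGINCCMRFQIEFPCLHKYKFIFPWDGMRCRYVPRT
RGAECFWRCIETLSCHLRHKLIWWPQSHGLGQPILHGATVFGCARVVMYSKNHYVMRAEE
AHVGRAIFGFMQEFSFQMFSFPHKYICAKRQYQEAWSAGSQMPTDEIRSWQMLAYLVFEY
LAYGWKSKVDFFLNEGRTTIRAIHGEPLWNDCWSPDTLHTKQWYHKFKAWCGCVHPIGSE
MVKSTGHYFWTLHDHWFSDHFEVHMEVGRCQLVGTLFDSTISMRMGCSNIYDECSYIFRH
PKAINIIAFYMGSKEQMKCSMFQAIWEKHNFQEVVSVAGTLVFMTNTGVPLMCEWMMDKY
SIVMPHCIQFHYPGDCAEPNSRTVWHGQPCYAKTTIWNDSHPCRVVNLDTTSVTSIIQMR
WIANVGKYMQYLTRAGPVIGWYMDDQSWSLRRPNTLQSVNQEVDDLCQCRWCFPNSCCEG
IAFPNCLQAQKPIEVVDLSQLNGWKWELWKSAWMMEYNTCKYVEVAKRCPCNWHFLKPYR
LTNEAPAHGAMKQSGHMQTCMDTINILLMLRWCCQIVIPLTRCCTADYRLHMIMRGKVAN
FFVSMTQYHCWGRYEPPFSRPKIFHCVFMCNSYEAQPNMDSEWPDVYTFCPTNYTNCETP
CCTEQRSTSTSNKGALERHESTFIRQPLGAPQWGMLFGSLQNTELQPMFQSSGNDSPIKD
DLYSDLWHCNHDKFAYRDCIPNQHQWWLHAKQIGTRLCMDFTCAGRTDNRAFLCIALTHR
DENKAAFWRHPGARVACNQKSSERMFSIVRYISKGHWYCSDEIIYPLIIEQYSAFEVDDG
GMRAHYVCIGRIDFFIKCVWTMTGRTPQAIDAGWEMLEYPYLWHIAQSGHTSDENFATKS
IASKCIPQLVIQANYKLRPWGNETWWMCNDMNKVMLMLGCYCIKTFKFSEVAGSMSNLTA
CQRGMDMFQTDPIADWYGKGKSDALFDSNTLLINKTQEEDTAAVSGEEHWDMEPQQTLAT
WIMCAVVEWIFCSPSECVDLDTVCNVCTVFYMVGCHTMTYDMHQIMCQMPAFAMWEGMPY
RHDLCYTYFRPTWHCPQNHEKHSAWSQNMKKIEKPCYHDHLQGQMMHDRFVVPNEKMKQI
NTWAHLDRGPCANHWFMSHRIFKMFWGRLCEQTQEPDFYKVAHYKSTGDIWYPENPHRHE
DQKFADWPSEKEDDIEQFERPDYHIYFVRGKRGFGSNVDILHGLFNDMAMIIDLSVKYCM
FWYARNHHTCWRGFDWSGHNEKAPFWRFEGRQLATPNKQKPCPCYVAAREWWFPDNVLKN
NYKPRHCICLKKIIPNSRDMQIYWGDIFWIRRDRDVHQYFKARHQLIHPHCGTEYAWVGA
DSYIRLKYGKDIECSQQQDDQHKKKHFKPNPEWYDRLEYSGVSGGCASTINDEPAYFDSA
EVQCWWLQSMLLQGDLEPWSVVCFNSLLPGPGNPCPLWKNSHPNQGWVCGMYEVYNHFWV
IVYKWITCIQQIIGGWCQWNLTEGVFVHHYRLAPSLDRPWWCHTIHLDCTMHNVLIEALE
WNEWHYDQARGHDDLIEQEACPDPPIHNFDWVRVIVWGKLNVLTERVDRHEKRQVNIISQ
EIIREKIIVESVVCYTHWCCPCGEGGNPNNVQERRFIMYMMPNFGYEIHLSAHMNWQRHV
ANLQCDHKTMKNFPPWHSVPCGQGQCFWFRVGRWEYWVNIYAFNAPHWNDVNEGWMTMEG
RWRRPFMQAQNRVFEIDFGHSHGDSWILWGTLTNADSMCELCMGHLMRSSGDGPTFFFDC
MGFNFSFFVNGNIAYHNPMTTAEYLRYSRVPECPVDYKPAIHHCANVLDIELMACDVCEY
QDYDRPRMRIVEMVPLWSSDAYQNTCGKHGSGWHNCWSSYMIRELSWQIWIESMDKHFVR
IGMNDVKARQIYSGNPVERMSKHVNFVQGFHEDDQIAVYRWHNPLNHPNMAYKAGVMWEM
SRGGFVWIWHARFQCACRQTYETEQGGTTGLCAKKKIHGNLAVIRCLYNLLKMFKCDQGR
YAPWRWDDFMKWDTDNLSLITNIRDGVHAWHREMGFNPEYADPMNVGWTITIRSMTPEIT
IKTWGTDWKWKMSFLLPFFVEDLCNGTITHNWDYHSEWIDHSSYYQRKNDQWGKVCCTLV
VYGYSNNFNKSFNDTGHITVKLMFNNKTEPKNANQQHNDVYNQWVLHAIWYADHVKSMWE
SEYLWSPEQPYMSLPVALCEIKSTMQALTLFCCAILMVKECHCQHNSYECPKRVDQAYYV
NGNFQHDFHIRCCNVLEAWLYDLYPNRKGLDPKYGAEAINNCTGQMWMPHMDGAVQDSQL
DWNNAYFDWETREVILNELQTKRVCADISHSGAHQKDQHTDITFGHPEVMFCLCGHGAMM
CPLAVREDYWLLPPTCNANDHMYKVHDYAGAKGCITEGFQFCFDRRALMLMACGGFDRNI
VECHIVTSN
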