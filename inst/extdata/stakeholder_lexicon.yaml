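# Stakeholder keyword lexicon, in matching priority order (first hit wins).
# Keywords are matched case-insensitively as substrings of the concatenated
# profile text (authentication + introduction + tags). The fallback type
# common_personnel matches anything left over and must stay last.
government:
  - government
  - police
  - court
  - judicial bureau
  - judicial office
  - procuratorate
  - commission for discipline inspection
  - political and legal committee
hospital:
  - hospital
traditional_media:
  - newspaper
  - radio
  - TV station
  - news
  - magazine
  - broadcast
  - daily
  - timely
  - weekly
  - monthly
  - morning post
  - evening post
  - channel
we_media:
  - We-media
  - author
  - writer
  - reporter
  - editor
  - blogger
  - commentator
  - critic
platform_account:
  - Sina Weibo
  - Weibo medical and health operation
  - Weibo secretary
  - Weibo administrator
  - Weibo rumor rebuttal
  - Weibo politics
social_organization:
  - association
  - public welfare
medical_company:
  - vaccine manufacturer
  - Sinovac
  - CanSino
  - Hualan
  - Zhifei
  - Kangtai
  - medical enterprise
common_company:
  - company
  - enterprise
educational_institution:
  - middle school
  - high school
  - campus
  - technical school
medical_personnel:
  - doctor
  - nurse
common_personnel: []
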